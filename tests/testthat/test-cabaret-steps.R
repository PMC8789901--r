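# scalar-loop transcription of the flux formulas (extrapolation, two-sided
# limiter, monotonicity cap) used as an independent oracle for the vectorized
# implementation
oracle_fluxes <- function(u, U, Uh, Ai_n, m_n, Q, tau, h, f, finv_unused) {
  J <- length(U)
  out <- numeric(J)
  clamp <- function(x, a, b) min(max(x, a), b)
  for (k in 1:J) {                       # flux node k (1-based like the math)
    ubar_np1 <- 2 * Uh[k] - u[k]
    mid <- clamp(0.5 * (u[k + 1] + ubar_np1), 0, 1)
    fb <- f(mid)
    m_ <- min(f(U[k]), f(u[k + 1]))
    M_ <- max(f(U[k]), f(u[k + 1]))
    ft <- clamp(fb, m_, M_)
    if (k >= 2) {
      s1 <- f(U[k - 1]); s2 <- f(u[k]); s3 <- f(U[k]); s4 <- f(u[k + 1])
      phi <- Ai_n[k] * m_n[k] * (U[k] - u[k]) / ((tau / h) * Q)
      if (s1 <= s2 && s2 <= s3 && s3 <= s4) {
        ft <- min(ft, s2 + phi)
      } else if (s1 >= s2 && s2 >= s3 && s3 >= s4) {
        ft <- max(ft, s2 + phi)
      }
    }
    out[k] <- ft
  }
  out
}

test_that("CFL step follows r h / max speed and clips to breakpoints", {
  g <- grid1d(1, 100)
  flds <- stage_fields(g, unit_model())
  lin <- linear_ff()
  expect_equal(cfl_timestep(flds, Q = 2, lin, r = 0.5), 0.0025)
  expect_equal(cfl_timestep(flds, Q = 4, lin, r = 0.5), 0.00125)
  expect_equal(cfl_timestep(flds, Q = 2, lin, r = 0.5, t = 0,
                            breakpoints = c(0.001, 5)), 0.001)
  # degenerate flux speed with no breakpoints ahead raises
  ffdeg <- quad_mobility_ff()              # f'(1) = 0 at the uniform state
  expect_error(cfl_timestep(flds, Q = 1, ffdeg, r = 0.5), "zero")
})

test_that("mixture flow is the sum of injection and healthy-bed inflow", {
  m <- unit_model()
  expect_equal(mixture_flow(2, 0.5, m), 3)
  expect_equal(mixture_flow(0, 0.3, m), m$qbar_b(0.3))
  qb <- m$qbar_b(0.7)
  expect_equal(mixture_flow(qb, 0.7, m), 2 * qb)
  expect_error(mixture_flow(-5, 0.5, m), "positive")
})

test_that("discrete pressure telescopes to the closed Darcy form at S = 1", {
  K <- patient_fixture("K")
  ff <- build_fractional_flow(K)
  g <- grid1d(K$L, 100)
  flds <- stage_fields(g, K)               # S = 1 everywhere
  Q <- K$qbar_b(1)
  A <- K$A1(0)
  closed <- K$p2(1) + Q * K$eta_b * K$L / (K$K * A) / 1333.22
  expect_equal(discrete_pressure(flds, Q, K, ff), closed, tolerance = 1e-12)
  # halving the permeability doubles the Darcy term
  K2 <- patient_fixture("K"); K2$K <- K$K / 2
  d1 <- discrete_pressure(flds, Q, K, ff) - K$p2(1)
  flds2 <- stage_fields(g, K2)
  d2 <- discrete_pressure(flds2, Q, K2, ff) - K2$p2(1)
  expect_equal(d2, 2 * d1, tolerance = 1e-12)
  # vanishing flow leaves only the outlet pressure
  expect_equal(discrete_pressure(flds, 1e-300, K, ff), K$p2(1), tolerance = 1e-10)
})

test_that("half step reproduces the hand-computed two-point difference", {
  m <- unit_model()
  g <- grid1d(1, 2)                         # h = 0.5
  flds <- stage_fields(g, m, u = c(1, 0.5, 0), U = c(0.75, 0.25))
  got <- half_step(flds, Q = 1, tau = 0.25, linear_ff())
  expect_equal(got, c(0.875, 0.375))
  # doubling tau doubles the increment
  got2 <- half_step(flds, Q = 1, tau = 0.5, linear_ff())
  expect_equal(got2 - flds$U, 2 * (got - flds$U))
  # uniform state is untouched
  fldsu <- stage_fields(g, m, u = 0.6, U = 0.6)
  expect_equal(half_step(fldsu, Q = 3, tau = 0.1, quad_mobility_ff()),
               c(0.6, 0.6))
})

test_that("inlet flux is the healthy-bed share of the mixture flow", {
  m <- unit_model()
  g <- grid1d(1, 4)
  flds <- stage_fields(g, m, u = 1, U = c(1, 1, 0.5, 0.5))
  qb <- m$qbar_b(psi_mean_ <- (g$h / g$L) * sum(flds$U))
  b0 <- boundary_flux(0, flds$U, flds, m)
  expect_equal(b0$f0, 1)
  expect_equal(b0$Vbar, 0.75)
  expect_equal(boundary_flux(qb, flds$U, flds, m)$f0, 0.5)
  expect_equal(boundary_flux(3 * qb, flds$U, flds, m)$f0, 0.25)
})

test_that("interior fluxes match an independent scalar transcription", {
  set.seed(11)
  m <- unit_model()
  for (ff in list(linear_ff(), quad_mobility_ff())) {
    for (rep in 1:5) {
      J <- 4
      g <- grid1d(1, J)
      # monotone-ish state with a front, plus noise cases
      u <- sort(runif(J + 1))
      U <- pmin(pmax((u[1:J] + u[2:(J + 1)]) / 2 + runif(J, -0.1, 0.1), 0), 1)
      if (rep >= 4) { u <- rev(u); U <- rev(U) }
      flds <- stage_fields(g, m, u = u, U = U)
      Q <- 1; tau <- 0.1
      Uh <- half_step(flds, Q, tau, ff)
      got <- interior_fluxes(flds, Uh, Q, tau, ff)
      want <- oracle_fluxes(u, U, Uh, flds$Ai_nodes, flds$m_nodes,
                            Q, tau, g$h, ff$f)
      expect_equal(got, want, tolerance = 1e-14)
    }
  }
})

test_that("uniform states are flux equilibria of the whole sub-stage chain", {
  m <- unit_model()
  g <- grid1d(1, 8)
  ff <- quad_mobility_ff()
  for (cval in c(0.3, 1)) {
    flds <- stage_fields(g, m, u = cval, U = cval)
    Q <- 1; tau <- cfl_timestep(flds, Q, ff, r = 0.5, breakpoints = 1)
    Uh <- half_step(flds, Q, tau, ff)
    expect_equal(Uh, rep(cval, g$J))
    fx <- interior_fluxes(flds, Uh, Q, tau, ff)
    expect_equal(fx, rep(ff$f(cval), g$J))
    U1 <- full_step(flds, c(ff$f(cval), fx), Q, tau)
    expect_equal(U1, rep(cval, g$J))
    u1 <- flux_variable_update(flds, U1, fx, ff$f(cval), ff)
    expect_equal(u1, rep(cval, g$J + 1), tolerance = 1e-12)
  }
})

test_that("full step is conservative bookkeeping of flux differences", {
  m <- unit_model()
  g <- grid1d(1, 5)
  flds <- stage_fields(g, m, u = seq(1, 0, length.out = 6),
                       U = seq(0.9, 0.1, length.out = 5))
  # equal fluxes leave the cells untouched
  expect_equal(full_step(flds, rep(0.4, 6), Q_half = 2, tau = 0.05), flds$U)
  # a single flux difference moves exactly tau*Q/(m A h) * df
  fx <- rep(0.4, 6); fx[3] <- 0.5
  got <- full_step(flds, fx, Q_half = 2, tau = 0.05)
  expect_equal(got[2] - flds$U[2], -0.05 * 2 * 0.1 / g$h)
  expect_equal(got[3] - flds$U[3], +0.05 * 2 * 0.1 / g$h)
})

test_that("flux-variable update clamps extrapolation into the new cell bracket", {
  m <- unit_model()
  g <- grid1d(1, 3)
  lin <- linear_ff()
  flds <- stage_fields(g, m, u = c(0.2, 0.4, 0.6, 0.8), U = c(0.3, 0.5, 0.7))
  U1 <- c(0.35, 0.55, 0.75)
  # fluxes whose preimages extrapolate far above the brackets
  fx <- c(0.9, 0.9, 0.9)
  u1 <- flux_variable_update(flds, U1, fx, f0_new = 0.1, lin)
  expect_equal(u1[1], 0.1)                  # inlet: f^-1 of the inlet flux
  expect_equal(u1[2], 0.55)                 # clamped to max(U1[1], U1[2])
  expect_equal(u1[4], max(U1[3], flds$u[4]))# outlet: one-sided bracket
})
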