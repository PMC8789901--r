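test_that("linear advection at r = 1 is node-exact for an injected affine ramp", {
  lin <- linear_ff()
  m <- unit_model()
  g <- grid1d(1, 50)
  flds <- stage_fields(g, m)
  cc <- 0.4
  gfun <- function(t) 1 - cc * t
  exact <- function(x, t) ifelse(x >= t, 1, 1 - cc * (t - x))
  t <- 0
  for (n in 1:60) {
    res <- cabaret_run(flds, lin, duration = g$h,
                       flow_fun = function(t2, V) 1,
                       inlet_fun = function(tb, te, V) gfun(t + te),
                       r = 1, max_steps = 5, record = FALSE)
    flds <- res$fields
    t <- t + g$h
    expect_lt(max(abs(flds$u - exact(g$x_nodes, t))), 1e-12)
    expect_lt(max(abs(flds$U - exact(g$x_half, t))), 1e-12)
  }
})

test_that("Riemann displacement converges to the Welge solution", {
  ff <- quad_mobility_ff()
  w <- bl_riemann_solution(ff, SL = 0, SR = 1, c = 1)
  # tangency: the shock chord slope equals the characteristic speed at s1
  s1 <- w$s_tangent
  expect_equal(ff$df(s1), (1 - ff$f(s1)) / (1 - s1), tolerance = 1e-8)
  Tfin <- 0.5 / w$shock_speed
  l1 <- sapply(c(50, 100), function(J) {
    rr <- riemann_run(J, ff, Tfin)
    sum(abs(rr$fields$U - w$profile(rr$grid$x_half, Tfin))) * rr$grid$h
  })
  expect_gt(l1[1] / l1[2], 1.5)                 # first-order at the shock
  rr <- riemann_run(100, ff, Tfin)
  xs <- shock_position(rr$fields$u, rr$grid$x_nodes, w$s_tangent)
  expect_lt(abs(xs - 0.5) / 0.5, 0.02)
})

test_that("the scheme preserves [0, 1] and total variation on Riemann data", {
  ff <- quad_mobility_ff()
  m <- unit_model()
  g <- grid1d(1, 50)
  flds <- stage_fields(g, m)
  # compose the exported sub-stage operations directly (no engine-side
  # clamping) so the limiters alone must maintain the bounds
  t <- 0
  tv_prev <- NULL
  for (n in 1:80) {
    Q <- 1
    tau <- cfl_timestep(flds, Q, ff, r = 0.5, extra_speed = ff$df_max)
    Uh <- half_step(flds, Q, tau, ff)
    fx <- interior_fluxes(flds, Uh, Q, tau, ff)
    U1 <- full_step(flds, c(0, fx), Q_half = Q, tau = tau)
    u1 <- flux_variable_update(flds, U1, fx, f0_new = 0, ff)
    expect_true(all(u1 >= -1e-12 & u1 <= 1 + 1e-12))
    expect_true(all(U1 >= -1e-12 & U1 <= 1 + 1e-12))
    tv <- sum(abs(diff(u1)))
    if (!is.null(tv_prev)) expect_lte(tv, tv_prev + 1e-10)
    tv_prev <- tv
    flds$u <- u1; flds$U <- U1
    t <- t + tau
  }
})

test_that("identical inputs give bit-identical traces", {
  K <- patient_fixture("K")
  ff <- build_fractional_flow(K)
  plan <- control_plan(stage_control(1.5, 0.5, 1), epsilon = 0.1)
  g <- grid1d(K$L, 40)
  a <- run_stage(K, ff, plan, 1, g, engine = "reference")
  b <- run_stage(K, ff, plan, 1, g, engine = "reference")
  expect_identical(a$trace, b$trace)
  expect_identical(a$fields$u, b$fields$u)
  ac <- run_stage(K, ff, plan, 1, g, engine = "compiled")
  bc <- run_stage(K, ff, plan, 1, g, engine = "compiled")
  expect_identical(ac$trace, bc$trace)
})

test_that("compiled and reference engines implement the same scheme", {
  K <- patient_fixture("K")
  ff <- build_fractional_flow(K)
  g <- grid1d(K$L, 60)
  for (st in list(stage_control(0, 1, 2),          # no injection
                  stage_control(1.2, 0.8, 1.5),    # trapezoid
                  stage_control(3, 0, 1))) {       # bang profile
    plan <- control_plan(st, epsilon = 0.1)
    a <- run_stage(K, ff, plan, 1, g, engine = "reference")
    b <- run_stage(K, ff, plan, 1, g, engine = "compiled")
    expect_equal(a$steps, b$steps)
    expect_lt(max(abs(a$fields$u - b$fields$u)), 1e-10)
    expect_lt(max(abs(a$fields$U - b$fields$U)), 1e-10)
    expect_lt(max(abs(a$trace$p1 - b$trace$p1), na.rm = TRUE), 1e-9)
    expect_equal(a$min_S_outlet, b$min_S_outlet, tolerance = 1e-10)
  }
})

test_that("a runaway time step hits the configurable cap", {
  K <- patient_fixture("K")
  ff <- build_fractional_flow(K)
  plan <- control_plan(stage_control(2, 1, 3), epsilon = 0.1)
  g <- grid1d(K$L, 50)
  expect_error(run_stage(K, ff, plan, 1, g, max_steps = 10), "cap")
  expect_error(run_stage(K, ff, plan, 1, g, max_steps = 10,
                         engine = "reference"), "cap")
})
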