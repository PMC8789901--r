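#' Uniform 1-D grid
#'
#' `J` cells of width `h = L / J`; flux variables live on the `J + 1` integer
#' nodes `x_j = j h`, conservative variables on the `J` half-integer nodes
#' `x_{j+1/2}`.
#'
#' @param L domain length (cm).
#' @param J number of cells (>= 2).
#' @return An object of class `grid1d` with `J`, `h`, `x_nodes`, `x_half`.
#' @export
grid1d <- function(L, J) {
  stopifnot(L > 0, J >= 2)
  J <- as.integer(J)
  h <- L / J
  structure(list(J = J, h = h, L = L,
                 x_nodes = h * (0:J),
                 x_half = h * ((0:(J - 1)) + 0.5)),
            class = "grid1d")
}

#' Stage field container
#'
#' Holds the staggered CABARET state for one embolization stage: flux
#' variables `u` (length `J + 1`, integer nodes) and conservative variables
#' `U` (length `J`, half-integer nodes), both blood saturations in `[0, 1]`
#' relative to the stage cross-section `A_i`, plus the sampled geometry.
#'
#' @param grid a [grid1d()].
#' @param model a [patient_model()] (supplies `A1(x)` and `m(x)`).
#' @param Ai_nodes,Ai_half stage cross-section at integer / half-integer
#'   nodes; defaults to the initial cross-section `A1`.  Floored at
#'   `1e-6 * A1`.
#' @param u,U initial saturations (scalars or full vectors); default 1
#'   (only blood in the newly available lumen at each stage start).
#' @return An object of class `stage_fields`.
#' @export
stage_fields <- function(grid, model, Ai_nodes = NULL, Ai_half = NULL,
                         u = 1, U = 1) {
  stopifnot(inherits(grid, "grid1d"), inherits(model, "patient_model"))
  A1n <- model$A1(grid$x_nodes)
  A1h <- model$A1(grid$x_half)
  Ai_nodes <- Ai_nodes %||% A1n
  Ai_half <- Ai_half %||% A1h
  Ai_nodes <- pmax(Ai_nodes, A_FLOOR * A1n)
  Ai_half <- pmax(Ai_half, A_FLOOR * A1h)
  if (any(Ai_nodes > A1n + 1e-12) || any(Ai_half > A1h + 1e-12))
    stop("stage cross-section A_i must not exceed the initial cross-section A1")
  u <- if (length(u) == 1L) rep.int(u, grid$J + 1L) else u
  U <- if (length(U) == 1L) rep.int(U, grid$J) else U
  stopifnot(length(u) == grid$J + 1L, length(U) == grid$J,
            all(u >= 0 & u <= 1), all(U >= 0 & U <= 1))
  structure(list(grid = grid, u = u, U = U,
                 Ai_nodes = Ai_nodes, Ai_half = Ai_half,
                 A1_nodes = A1n, A1_half = A1h,
                 m_nodes = model$m(grid$x_nodes),
                 m_half = model$m(grid$x_half)),
            class = "stage_fields")
}

# mean blood fraction of the ORIGINAL cross-section, from conservative values
psi_mean <- function(fields, U = fields$U) {
  g <- fields$grid
  (g$h / g$L) * sum(U * fields$Ai_half / fields$A1_half)
}

#' CFL time step
#'
#' `tau = r h / max_j a(x_{j+1/2})` with local characteristic speed
#' `a = Q f'(U) / (m A_i)` evaluated at the conservative values.  The step is
#' additionally clipped so that the next time lands exactly on any control
#' breakpoint (ramp kinks, stage end) in `breakpoints` that lies ahead of the
#' current local time `t`.
#'
#' @param fields a [stage_fields()].
#' @param Q mixture flow (cm^3/s, > 0).
#' @param ff a [fractional_flow()].
#' @param r CFL number in (0, 1].
#' @param t current local time (s), used only for breakpoint clipping.
#' @param breakpoints sorted times (s) the stepping must hit exactly.
#' @param extra_speed additional characteristic speed (1/s scale) included in
#'   the maximum.  While the inlet is injecting, the state the boundary is
#'   about to introduce can move faster than any speed present in the current
#'   (possibly still uniform) field — e.g. `f'(1) = 0` at the all-blood
#'   startup state — so the caller adds the fastest incoming wave speed
#'   `Q f'_max / (m A_i)` at the inlet here.
#' @param tau_floor lower bound on the step (s), applied before breakpoint
#'   clipping.  The engines pass `duration / 200000` so that any stage
#'   terminates within a fixed resolution budget; physically resolved regimes
#'   never touch the floor.
#' @return Time step `tau` (s).
#' @export
cfl_timestep <- function(fields, Q, ff, r, t = 0, breakpoints = NULL,
                         extra_speed = 0, tau_floor = 0) {
  stopifnot(r > 0, r <= 1, Q > 0)
  # effectively occluded cells (lumen < 1% of A1) do not bind the step; their
  # speeds scale as 1/A_i while their weight in all functionals is < 1e-2
  Ai_eff <- pmax(fields$Ai_half, CFL_A_FRAC * fields$A1_half)
  a <- Q * ff$df(fields$U) / (fields$m_half * Ai_eff)
  amax <- max(a, extra_speed)
  if (!is.finite(amax) || amax <= 0) {
    if (is.null(breakpoints))
      stop("maximum characteristic speed is zero or non-finite; degenerate flux")
    # nothing moves: jump straight to the next control breakpoint
    amax <- 0
  }
  tau <- if (amax > 0) r * fields$grid$h / amax else Inf
  tau <- max(tau, tau_floor)
  if (!is.null(breakpoints)) {
    ahead <- breakpoints[breakpoints > t + 1e-12]
    if (length(ahead)) tau <- min(tau, ahead[1] - t)
  }
  if (!is.finite(tau))
    stop("maximum characteristic speed is zero and no breakpoint lies ahead")
  tau
}

#' Mixture flow
#'
#' `Q = q_e + qbar_b(Vbar)`, the injected agent plus the healthy-bed blood
#' inflow at the current mean blood fraction of the original cross-section.
#'
#' @param q_e embolic agent inflow (cm^3/s, >= 0).
#' @param Vbar mean blood fraction `Psi-bar` in `[0, 1]`.
#' @param model a [patient_model()].
#' @return `Q > 0` (cm^3/s).
#' @export
mixture_flow <- function(q_e, Vbar, model) {
  stopifnot(Vbar >= -1e-12, Vbar <= 1 + 1e-12)
  Q <- q_e + model$qbar_b(min(max(Vbar, 0), 1))
  if (!is.finite(Q) || Q <= 0)
    stop("mixture flow must be positive; qbar_b violates its positivity contract")
  Q
}

# f(V)/k_b(V) with the fully-embolized-cell limit guarded by a saturation floor
fk_ratio <- function(ff, model, V) {
  V <- pmax(V, S_RATIO_FLOOR)
  ff$f(V) / model$kb(V)
}

#' Discrete inlet pressure
#'
#' Midpoint-rule Darcy drop added to the outlet pressure:
#' `p1 = p2(Vbar) + (Q eta_b / K) * sum_j f(V_{j+1/2}) h / (A1 k_b(V_{j+1/2}))`
#' with `V = U A_i / A1` the blood fraction of the original cross-section.
#' The Darcy sum is computed in CGS (dyn/cm^2) and converted to mmHg.
#'
#' @param fields a [stage_fields()].
#' @param Q mixture flow (cm^3/s).
#' @param model a [patient_model()].
#' @param ff a [fractional_flow()].
#' @return Inlet pressure `p1` (mmHg).
#' @export
discrete_pressure <- function(fields, Q, model, ff) {
  stopifnot(Q > 0)
  V <- fields$U * fields$Ai_half / fields$A1_half
  darcy <- (Q * model$eta_b / model$K) *
    sum(fk_ratio(ff, model, V) * fields$grid$h / fields$A1_half)
  Vbar <- psi_mean(fields)
  model$p2(min(max(Vbar, 0), 1)) + darcy / DYN_PER_MMHG
}

#' Half-time-layer predictor for the conservative variables
#'
#' `U^{n+1/2} = U^n - (tau/2) Q^n / (m A_i) * (f(u_{j+1}) - f(u_j)) / h`.
#'
#' @param fields a [stage_fields()] at layer `n`.
#' @param Q mixture flow at layer `n`.
#' @param tau time step (s).
#' @param ff a [fractional_flow()].
#' @return Conservative values at the half layer (length `J`).
#' @export
half_step <- function(fields, Q, tau, ff) {
  fu <- ff$f(fields$u)
  fields$U - (0.5 * tau) * Q / (fields$m_half * fields$Ai_half) *
    diff(fu) / fields$grid$h
}

#' Inlet numerical flux from the integral boundary condition
#'
#' Second-order approximation of the nonstandard inlet condition:
#' `f_0 = qbar_b(Vbar) / (q_e + qbar_b(Vbar))` where `Vbar` is the mean blood
#' fraction computed from the supplied conservative values (half or full
#' layer).  Following the reference discretization, `q_e` is evaluated at the
#' *base* layer `t^n` even when `Vbar` is taken at the half layer.
#'
#' @param q_e agent inflow at `t^n` (cm^3/s).
#' @param U_half conservative values to average (length `J`).
#' @param fields a [stage_fields()] (geometry).
#' @param model a [patient_model()].
#' @return `list(f0 = <flux in (0, 1]>, Vbar = <mean blood fraction>)`.
#' @export
boundary_flux <- function(q_e, U_half, fields, model) {
  Vbar <- psi_mean(fields, U_half)
  qb <- model$qbar_b(min(max(Vbar, 0), 1))
  list(f0 = qb / (q_e + qb), Vbar = Vbar)
}

#' Interior numerical fluxes with two-sided limiting and monotonicity cap
#'
#' For each interior/outlet node `j = 1..J`: extrapolate
#' `ubar_j^{n+1} = 2 U_{j-1/2}^{n+1/2} - u_{j-1}^n`, form the preliminary flux
#' `f(( u_j^n + ubar_j^{n+1} ) / 2)`, clamp it into
#' `[min, max](f(U_{j-1/2}^n), f(u_j^n))` (two-sided limiter), and then — only
#' where the four-point layer-`n` flux sequence
#' `f_{k-3/2}, f_{k-1}, f_{k-1/2}, f_k` is monotone (checked non-strictly,
#' nondecreasing branch first) — cap above (resp. floor below) by
#' `f(u_{k-1}^n) + phi_{k-1}^n`, with
#' `phi_{k-1}^n = A_i m (U_{k-1/2}^n - u_{k-1}^n) / (r^n Q^n)`,
#' `r^n = tau/h`.  The cap enforces the local monotonicity bound
#' `U_{k-1/2}^{n+1} >= u_{k-1}^n` (resp. `<=`), is exact on constants, and is
#' equality-tight for linear advection at `r = 1` so node-exact transport
#' survives the correction.  The four-point stencil exists for `k >= 2` only;
#' at `k = 1` and `k = J` just the two-sided limiter applies.
#'
#' @param fields a [stage_fields()] at layer `n`.
#' @param U_half conservative values at the half layer.
#' @param Q mixture flow at layer `n`.
#' @param tau time step (s).
#' @param ff a [fractional_flow()].
#' @return Numerical fluxes `f_j^{n+1/2}`, `j = 1..J` (length `J`).
#' @export
interior_fluxes <- function(fields, U_half, Q, tau, ff) {
  g <- fields$grid; J <- g$J
  u <- fields$u; U <- fields$U
  # j = 1..J: ubar_j^{n+1} = 2 U_{j-1/2}^{n+1/2} - u_{j-1}^n
  ubar_next <- 2 * U_half - u[1:J]
  # extrapolation can overshoot [0, 1] near shocks; the flux is only defined
  # on [0, 1] and the two-sided limiter would clamp such values anyway
  mid <- pmin(pmax(0.5 * (u[2:(J + 1)] + ubar_next), 0), 1)
  fbar <- ff$f(mid)
  fU <- ff$f(U)             # f_{j-1/2}^n for j = 1..J
  fu <- ff$f(u)             # f_j^n at R index j+1
  lo <- pmin(fU, fu[2:(J + 1)])
  hi <- pmax(fU, fu[2:(J + 1)])
  ftil <- pmin(pmax(fbar, lo), hi)

  if (J >= 2L) {
    k <- 2:J
    a1 <- fU[k - 1L]        # f_{k-3/2}^n
    a2 <- fu[k]             # f_{k-1}^n
    a3 <- fU[k]             # f_{k-1/2}^n
    a4 <- fu[k + 1L]        # f_k^n
    nondec <- a1 <= a2 & a2 <= a3 & a3 <= a4
    noninc <- a1 >= a2 & a2 >= a3 & a3 >= a4 & !nondec
    phi <- fields$Ai_nodes[k] * fields$m_nodes[k] *
      (U[k] - u[k]) / ((tau / g$h) * Q)
    cap <- a2 + phi
    fk <- ftil[k]
    fk[nondec] <- pmin(fk[nondec], cap[nondec])
    fk[noninc] <- pmax(fk[noninc], cap[noninc])
    ftil[k] <- fk
  }
  ftil
}

#' Full conservative update
#'
#' `U^{n+1} = U^n - tau Q^{n+1/2} / (m A_i) * (f_{j+1}^{n+1/2} - f_j^{n+1/2}) / h`
#' using the half-layer fluxes including the inlet flux.
#'
#' @param fields a [stage_fields()] at layer `n`.
#' @param fluxes all half-layer fluxes `c(f_0, f_1, ..., f_J)`
#'   (length `J + 1`).
#' @param Q_half mixture flow at the half layer.
#' @param tau time step (s).
#' @return Conservative values at layer `n + 1` (length `J`).
#' @export
full_step <- function(fields, fluxes, Q_half, tau) {
  stopifnot(length(fluxes) == fields$grid$J + 1L)
  fields$U - tau * Q_half / (fields$m_half * fields$Ai_half) *
    diff(fluxes) / fields$grid$h
}

#' Flux-variable update (seventh sub-stage)
#'
#' Inlet: `u_0^{n+1} = f^{-1}(f_0^{n+1})` with the boundary flux evaluated at
#' the full layer.  Interior: extrapolate `2 u_j^{n+1/2} - u_j^n` with
#' `u_j^{n+1/2} = f^{-1}(f_j^{n+1/2})` and clamp into the interval spanned by
#' the neighboring new conservative values `U_{j-1/2}^{n+1}, U_{j+1/2}^{n+1}`.
#' At the outlet `j = J` (no right cell; all characteristics leave the
#' domain) the bracket is `[min, max](U_{J-1/2}^{n+1}, u_J^n)`, which is
#' one-sided in space and exact on affine profiles.
#'
#' @param fields a [stage_fields()] at layer `n`.
#' @param U_new conservative values at layer `n + 1`.
#' @param f_interior half-layer fluxes `f_j^{n+1/2}`, `j = 1..J`.
#' @param f0_new inlet flux at the full layer `n + 1`.
#' @param ff a [fractional_flow()].
#' @return Flux variables at layer `n + 1` (length `J + 1`).
#' @export
flux_variable_update <- function(fields, U_new, f_interior, f0_new, ff) {
  g <- fields$grid; J <- g$J
  u <- fields$u
  u_half <- ff$finv(f_interior)
  util <- 2 * u_half - u[2:(J + 1)]
  lo <- c(pmin(U_new[1:(J - 1)], U_new[2:J]), min(U_new[J], u[J + 1]))
  hi <- c(pmax(U_new[1:(J - 1)], U_new[2:J]), max(U_new[J], u[J + 1]))
  c(ff$finv(f0_new), pmin(pmax(util, lo), hi))
}
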