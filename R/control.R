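#' Per-stage injection control
#'
#' One embolization stage is parametrized by the triple
#' `(gamma, theta1, theta2)`: dimensionless injection intensity, ramp-up
#' duration and plateau duration (seconds).  The stage always ends with a
#' fixed ramp-down of duration `epsilon` (stored on the [control_plan()]), so
#' the stage lasts `theta1 + theta2 + epsilon` seconds.
#'
#' @param gamma injection intensity (>= 0); the injected agent flow is
#'   `gamma * Q(stage start) * E(t)`.
#' @param theta1 ramp-up duration (s, >= 0).  Below `1e-8` s the profile
#'   degenerates to the discontinuous ("bang") variant that jumps to the
#'   plateau immediately after the stage start.
#' @param theta2 plateau duration (s, >= 0).
#' @return An object of class `stage_control`.
#' @export
stage_control <- function(gamma, theta1, theta2) {
  v <- c(gamma = gamma, theta1 = theta1, theta2 = theta2)
  if (any(!is.finite(v)) || any(v < 0))
    stop("stage control parameters (gamma, theta1, theta2) must be finite and nonnegative")
  structure(as.list(v), class = "stage_control")
}

#' Multi-stage control plan
#'
#' @param stages a list of [stage_control()] objects (or a single one), in
#'   chronological order.
#' @param epsilon terminal ramp-down duration (s, > 0); fixed at 0.1 s by
#'   default to reflect the quick stop of agent supply at each stage end, and
#'   never an optimization variable.
#' @return An object of class `control_plan`.
#' @export
control_plan <- function(stages, epsilon = 0.1) {
  if (inherits(stages, "stage_control")) stages <- list(stages)
  stopifnot(length(stages) >= 1L,
            all(vapply(stages, inherits, logical(1), "stage_control")),
            is.numeric(epsilon), length(epsilon) == 1L, epsilon > 0)
  structure(list(stages = stages, epsilon = epsilon), class = "control_plan")
}

#' @export
print.control_plan <- function(x, ...) {
  cat(sprintf("<control_plan: %d stage(s), epsilon = %g s>\n",
              length(x$stages), x$epsilon))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    cat(sprintf("  stage %d: gamma = %.4g, theta1 = %.4g s, theta2 = %.4g s\n",
                i, s$gamma, s$theta1, s$theta2))
  }
  invisible(x)
}

# per-stage durations theta1 + theta2 + epsilon
stage_durations <- function(plan) {
  vapply(plan$stages, function(s) s$theta1 + s$theta2 + plan$epsilon, numeric(1))
}

#' Stage boundary times
#'
#' `T_0 = 0` and `T_i = T_{i-1} + theta1_i + theta2_i + epsilon`.
#'
#' @param plan a [control_plan()].
#' @return Numeric vector `c(T_0, ..., T_N)`, strictly increasing.
#' @export
stage_times <- function(plan) {
  stopifnot(inherits(plan, "control_plan"))
  c(0, cumsum(stage_durations(plan)))
}

#' Dimensionless injection profile of one stage
#'
#' The trapezoid profile `E_i(t)` on `[T_{i-1}, T_i]`: linear ramp-up over
#' `theta1`, plateau at 1, linear ramp-down to 0 over the final `epsilon`.
#' When `theta1` is numerically zero (below `1e-8` s) the discontinuous
#' variant is used: `E = 0` exactly at the stage start, 1 immediately after.
#'
#' @param plan a [control_plan()].
#' @param i stage index.
#' @param t time (global, in `[T_{i-1}, T_i]`); vectorized.
#' @return Profile value(s) in `[0, 1]`.
#' @export
ramp_profile <- function(plan, i, t) {
  stopifnot(inherits(plan, "control_plan"))
  Tb <- stage_times(plan)
  if (any(t < Tb[i] - 1e-10 | t > Tb[i + 1] + 1e-10))
    stop(sprintf("time outside stage %d interval [%g, %g]", i, Tb[i], Tb[i + 1]))
  s <- pmin(pmax(t - Tb[i], 0), Tb[i + 1] - Tb[i])
  st <- plan$stages[[i]]
  D <- st$theta1 + st$theta2 + plan$epsilon
  eps <- plan$epsilon
  E <- numeric(length(s))
  if (st$theta1 > THETA_SWITCH) {
    up <- s <= st$theta1
    E[up] <- s[up] / st$theta1
    plat <- s >= st$theta1 & s <= D - eps
  } else {
    plat <- s > 0 & s <= D - eps  # discontinuous variant: 0 at the start only
  }
  E[plat] <- 1
  down <- s > D - eps
  E[down] <- (D - s[down]) / eps
  pmin(pmax(E, 0), 1)
}

#' Embolic agent inflow of one stage
#'
#' `q_e(t) = gamma_i * Q_start * E_i(t)` where `Q_start = Q_i(T_{i-1})` is the
#' mixture flow at the stage start (which equals the healthy-bed inflow, since
#' the injection starts from zero).
#'
#' @param plan a [control_plan()].
#' @param i stage index.
#' @param Q_start mixture flow at stage start (cm^3/s, > 0).
#' @param t time (global, within the stage); vectorized.
#' @return Agent inflow (cm^3/s).
#' @export
embolic_flow <- function(plan, i, Q_start, t) {
  stopifnot(Q_start > 0)
  plan$stages[[i]]$gamma * Q_start * ramp_profile(plan, i, t)
}

#' Flatten / restore a control plan for the optimizer
#'
#' Stage-major ordering: `(gamma_1, theta1_1, theta2_1, gamma_2, ...)`.
#' `unpack_plan(pack_plan(plan), ...)` is the identity.
#'
#' @param plan a [control_plan()].
#' @return `pack_plan`: numeric vector of length `3 N`.
#' @export
pack_plan <- function(plan) {
  stopifnot(inherits(plan, "control_plan"))
  unlist(lapply(plan$stages, function(s) c(s$gamma, s$theta1, s$theta2)),
         use.names = FALSE)
}

#' @rdname pack_plan
#' @param x numeric vector of length `3 N`, all entries nonnegative.
#' @param epsilon terminal ramp-down duration (s).
#' @return `unpack_plan`: a [control_plan()].
#' @export
unpack_plan <- function(x, epsilon = 0.1) {
  if (!is.numeric(x) || length(x) < 3L || length(x) %% 3L != 0L)
    stop("control vector length must be a positive multiple of 3")
  if (any(x < 0)) stop("control vector entries must be nonnegative")
  stages <- lapply(seq_len(length(x) / 3L), function(i) {
    v <- x[(3L * (i - 1L) + 1L):(3L * i)]
    stage_control(v[1], v[2], v[3])
  })
  control_plan(stages, epsilon = epsilon)
}
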