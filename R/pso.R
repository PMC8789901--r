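#' Particle swarm configuration
#'
#' Parameters of the modified particle swarm method: subdomain
#' initialization, linearly decaying inertia `w^k = w1 - w2 k / I`,
#' nonnegativity clipping with velocity recomputation, and probabilistic
#' reinitialization of particles into their own subdomain.
#'
#' @param dim search-space dimension (for control problems, `3 N`).
#' @param M number of particles (one per initial subdomain).
#' @param I number of iterations.
#' @param P reinitialization probability per particle per iteration.
#' @param w1,w2 inertia schedule constants, `0 < w2 < w1 < 1`.
#' @param c1,c2 cognitive and social acceleration constants.
#' @param R penalty weight carried along for penalized objectives.
#' @param bounds per-coordinate upper bounds `b_l > 0` of the box
#'   `[0, b_1] x ... x [0, b_dim]` used for initialization/reinitialization
#'   (positions themselves are only constrained to be nonnegative).
#' @param seed RNG seed; the run is fully determined by it.
#' @param per_coordinate draw the random factors `r1, r2` per coordinate
#'   (default) or as per-particle scalars.
#' @return An object of class `swarm_config`.
#' @export
swarm_config <- function(dim, M = 16L, I = 300L, P = 0.15,
                         w1 = 0.9, w2 = 0.5, c1 = 1.49, c2 = 1.49,
                         R = 1000, bounds = NULL, seed = 1L,
                         per_coordinate = TRUE) {
  bounds <- bounds %||% rep(1, dim)
  stopifnot(dim >= 1, M >= 1, I >= 1, P >= 0, P <= 1,
            w2 > 0, w2 < w1, w1 < 1, c1 >= 0, c2 >= 0,
            length(bounds) == dim, all(bounds > 0))
  structure(list(dim = as.integer(dim), M = as.integer(M), I = as.integer(I),
                 P = P, w1 = w1, w2 = w2, c1 = c1, c2 = c2, R = R,
                 bounds = bounds, seed = as.integer(seed),
                 per_coordinate = isTRUE(per_coordinate)),
            class = "swarm_config")
}

#' Default control-vector bounds
#'
#' The model only requires control parameters to be nonnegative; bounded
#' initialization subdomains additionally need upper bounds.  Defaults:
#' injection intensity `gamma <= 30`, ramp/plateau durations `<= 10` s.
#'
#' @param N number of stages.
#' @param gamma_max,theta_max per-coordinate caps.
#' @return Numeric vector of length `3 N` in stage-major order.
#' @export
control_bounds <- function(N, gamma_max = 30, theta_max = 10) {
  rep(c(gamma_max, theta_max, theta_max), N)
}

#' Disjoint initialization subdomains
#'
#' Slices the box `[0, b_1] x ... x [0, b_dim]` into `M` equal half-open
#' slabs along the first coordinate; pairwise disjoint, union = box.
#'
#' @param bounds per-coordinate upper bounds.
#' @param M number of subdomains.
#' @return List of `M` matrices `rbind(lo, hi)` (2 x dim).
#' @export
init_subdomains <- function(bounds, M) {
  stopifnot(M >= 1, all(bounds > 0))
  d <- length(bounds)
  lapply(seq_len(M), function(l) {
    lo <- numeric(d); hi <- bounds
    lo[1] <- (l - 1) * bounds[1] / M
    hi[1] <- l * bounds[1] / M
    rbind(lo = lo, hi = hi)
  })
}

# uniform draw in one subdomain (uses the current RNG stream)
.draw_in <- function(box) {
  stats::runif(ncol(box), box["lo", ], box["hi", ])
}

.eval_objective <- function(objective, x) {
  v <- objective(x)
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("objective returned a non-finite value")
  v
}

#' Initialize the swarm
#'
#' One uniform random position per subdomain, zero velocities, personal
#' bests equal to the positions, global best by argmin of the objective.
#' Uses the current RNG stream ([pso_optimize()] seeds it).
#'
#' @param config a [swarm_config()].
#' @param objective `function(x) -> value`.
#' @param subdomains from [init_subdomains()]; rebuilt from `config` if `NULL`.
#' @return A `swarm_state` list.
#' @export
init_swarm <- function(config, objective, subdomains = NULL) {
  subdomains <- subdomains %||% init_subdomains(config$bounds, config$M)
  M <- config$M; d <- config$dim
  x <- t(vapply(subdomains, .draw_in, numeric(d)))
  if (d == 1L) x <- matrix(x, ncol = 1L)
  val <- apply(x, 1L, function(row) .eval_objective(objective, row))
  g <- which.min(val)
  structure(list(x = x, v = matrix(0, M, d), p = x, p_value = val,
                 g = x[g, ], g_value = val[g], k = 0L,
                 subdomains = subdomains,
                 history = val[g]),
            class = "swarm_state")
}

#' One particle-swarm iteration
#'
#' Velocity update with inertia `w^k = w1 - w2 k / I`, position update,
#' clipping of negative coordinates to zero with velocity recomputed as the
#' realized displacement, strict personal-best replacement, global best by
#' argmin, then independent reinitialization of each particle (probability
#' `P`) into its own original subdomain with zero velocity.
#'
#' @param state a `swarm_state`.
#' @param config a [swarm_config()].
#' @param objective `function(x) -> value`.
#' @return The updated state (iteration counter advanced, history appended).
#' @export
pso_step <- function(state, config, objective) {
  M <- config$M; d <- config$dim
  w <- config$w1 - config$w2 * state$k / config$I
  if (config$per_coordinate) {
    r1 <- matrix(stats::runif(M * d), M, d)
    r2 <- matrix(stats::runif(M * d), M, d)
  } else {
    r1 <- matrix(stats::runif(M), M, d)
    r2 <- matrix(stats::runif(M), M, d)
  }
  gmat <- matrix(state$g, M, d, byrow = TRUE)
  vbar <- w * state$v + config$c1 * r1 * (state$p - state$x) +
    config$c2 * r2 * (gmat - state$x)
  xbar <- state$x + vbar
  xt <- pmax(xbar, 0)                    # printed clipping rule
  vt <- xt - state$x                     # velocity as realized displacement

  val <- apply(xt, 1L, function(row) .eval_objective(objective, row))
  better <- val < state$p_value          # strict: ties keep the old best
  state$p[better, ] <- xt[better, , drop = FALSE]
  state$p_value[better] <- val[better]
  g <- which.min(state$p_value)
  state$g <- state$p[g, ]
  state$g_value <- state$p_value[g]

  reinit <- stats::runif(M) < config$P
  for (j in which(reinit)) {
    xt[j, ] <- .draw_in(state$subdomains[[j]])
    vt[j, ] <- 0
  }
  state$x <- xt
  state$v <- vt
  state$k <- state$k + 1L
  state$history <- c(state$history, state$g_value)
  state
}

#' Run the modified particle swarm optimization
#'
#' Seeds the RNG from `config$seed`, initializes the swarm over the disjoint
#' subdomains and performs `I` iterations.  The global-best value history is
#' non-increasing by construction.
#'
#' @param config a [swarm_config()].
#' @param objective `function(x) -> value`, defined on the nonnegative box.
#' @return List with `par` (best position), `value`, `history`
#'   (length `I + 1`: initialization plus one entry per iteration) and the
#'   final `state`.
#' @export
pso_optimize <- function(config, objective) {
  stopifnot(inherits(config, "swarm_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  state <- init_swarm(config, objective)
  for (k in seq_len(config$I))
    state <- pso_step(state, config, objective)
  list(par = state$g, value = state$g_value, history = state$history,
       state = state)
}
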