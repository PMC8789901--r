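#' Cross-section linkage between successive stages
#'
#' The agent solidifies between stages, so the lumen available to the next
#' stage is `A_i = A_{i-1} * S_{i-1}(T_{i-1})`, nodewise, floored at
#' `1e-6 * A1` to keep `1/(m A_i)` finite in fully embolized cells.
#'
#' @param A_prev cross-section of the previous stage (vector).
#' @param S_final its terminal saturation at the same nodes, in `[0, 1]`.
#' @param A1 the original cross-section at the same nodes (floor reference).
#' @return The next stage's cross-section.
#' @export
link_stage <- function(A_prev, S_final, A1) {
  stopifnot(length(A_prev) == length(S_final), length(A1) == length(A_prev),
            all(S_final >= -1e-12), all(S_final <= 1 + 1e-12))
  pmax(A_prev * pmin(pmax(S_final, 0), 1), A_FLOOR * A1)
}

#' Objective: mean residual blood fraction
#'
#' `J_N = (1/L) * integral of Psi_N dx`, evaluated by the midpoint rule over
#' the half-integer nodes (exact for linear profiles).
#'
#' @param Psi_final terminal `Psi = S A_i / A1` at the half nodes.
#' @param grid a [grid1d()].
#' @return `J_N` in `[0, 1]`.
#' @export
objective_mean_psi <- function(Psi_final, grid) {
  stopifnot(length(Psi_final) == grid$J,
            all(Psi_final >= -1e-12), all(Psi_final <= 1 + 1e-12))
  (grid$h / grid$L) * sum(Psi_final)
}

#' Safety constraint indicators for one stage
#'
#' `I1 = 1` iff the outlet saturation ever dropped below `1 - 1e-6` (embolic
#' agent reached the vein); `I2 = 1` iff the inlet pressure ever exceeded the
#' critical pressure `p_star`.  Evaluated on the recorded per-step values;
#' with breakpoint-clipped stepping every control kink is sampled.
#'
#' @param trace a stage trace (data frame with `S_outlet`, `p1`), or the
#'   result list of [run_stage()].
#' @param model a [patient_model()].
#' @param tol_outlet tolerance on the outlet condition.
#' @return `c(I1 = 0/1, I2 = 0/1)`.
#' @export
check_constraints <- function(trace, model, tol_outlet = 1e-6) {
  if (is.list(trace) && !is.data.frame(trace) && !is.null(trace$trace)) {
    min_out <- trace$min_S_outlet
    max_p1 <- trace$max_p1
  } else {
    stopifnot(nrow(trace) > 0)
    min_out <- min(trace$S_outlet)
    max_p1 <- max(trace$p1, na.rm = TRUE)
  }
  c(I1 = as.integer(min_out < 1 - tol_outlet),
    I2 = as.integer(is.finite(max_p1) && max_p1 > model$p_star))
}

#' Penalized objective
#'
#' `J_hat = J_N + R * sum_i (I1_i + I2_i)` — the penalty formulation that
#' turns the constrained optimal control problem into box-constrained
#' minimization.
#'
#' @param J_N objective value in `[0, 1]`.
#' @param penalties matrix (stages x 2) or vector of 0/1 indicators.
#' @param R penalty weight (> 0), default 1000.
#' @return Penalized value.
#' @export
penalized_objective <- function(J_N, penalties, R = 1000) {
  stopifnot(R > 0)
  J_N + R * sum(penalties)
}

#' Simulate a full multi-stage embolization plan
#'
#' Runs the stages in order, linking cross-sections through the solidified
#' agent, and aggregates the objective, the per-stage safety indicators and
#' the penalized functional.  Deterministic.
#'
#' @param model a [patient_model()].
#' @param ff a [fractional_flow()]; built from the model if `NULL`.
#' @param plan a [control_plan()].
#' @param grid a [grid1d()]; defaults to `J = 100` cells on `[0, L]`.
#' @param r CFL number (default 0.5).
#' @param R penalty weight (default 1000).
#' @param record keep full per-step traces (default `TRUE`).
#' @param max_steps per-stage step cap.
#' @param engine solver path, see [run_stage()].
#' @return An object of class `plan_evaluation`: list with `J_N`, `J_hat`,
#'   `penalties` (N x 2 matrix), `stages` (per-stage [run_stage()] results),
#'   `Psi_final`, `grid`.
#' @export
simulate_plan <- function(model, ff = NULL, plan, grid = NULL, r = 0.5,
                          R = 1000, record = TRUE, max_steps = 500000L,
                          engine = c("auto", "compiled", "reference")) {
  engine <- match.arg(engine)
  stopifnot(inherits(model, "patient_model"), inherits(plan, "control_plan"))
  ff <- ff %||% build_fractional_flow(model)
  grid <- grid %||% grid1d(model$L, 100L)
  N <- length(plan$stages)
  A1n <- model$A1(grid$x_nodes)
  A1h <- model$A1(grid$x_half)
  Ai_nodes <- A1n
  Ai_half <- A1h

  stages <- vector("list", N)
  penalties <- matrix(0L, nrow = N, ncol = 2L,
                      dimnames = list(NULL, c("I1", "I2")))
  for (i in seq_len(N)) {
    res <- run_stage(model, ff, plan, i, grid, r = r,
                     Ai_nodes = Ai_nodes, Ai_half = Ai_half,
                     max_steps = max_steps, record = record, engine = engine)
    stages[[i]] <- res
    penalties[i, ] <- check_constraints(res, model)
    Ai_nodes <- link_stage(Ai_nodes, res$fields$u, A1n)
    Ai_half <- link_stage(Ai_half, res$fields$U, A1h)
  }
  Psi_final <- stages[[N]]$Psi
  J_N <- objective_mean_psi(Psi_final, grid)
  out <- list(J_N = J_N,
              J_hat = penalized_objective(J_N, penalties, R),
              penalties = penalties, stages = stages,
              Psi_final = Psi_final, grid = grid, R = R)
  class(out) <- "plan_evaluation"
  out
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat(sprintf("<plan_evaluation: %d stage(s)>\n", nrow(x$penalties)))
  cat(sprintf("  J_N = %.6f, J_hat = %.6f\n", x$J_N, x$J_hat))
  for (i in seq_len(nrow(x$penalties)))
    cat(sprintf("  stage %d: I1 = %d, I2 = %d, max p1 = %.2f mmHg, min S(L) = %.6f\n",
                i, x$penalties[i, 1], x$penalties[i, 2],
                x$stages[[i]]$max_p1, x$stages[[i]]$min_S_outlet))
  invisible(x)
}
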