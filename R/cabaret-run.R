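# local (stage-time) injection profile; s in [0, D], D = theta1 + theta2 + eps
profile_local <- function(st, eps, s) {
  D <- st$theta1 + st$theta2 + eps
  E <- numeric(length(s))
  if (st$theta1 > THETA_SWITCH) {
    up <- s <= st$theta1
    E[up] <- s[up] / st$theta1
    plat <- s >= st$theta1 & s <= D - eps
  } else {
    plat <- s > 0 & s <= D - eps
  }
  E[plat] <- 1
  down <- s > D - eps
  E[down] <- (D - s[down]) / eps
  pmin(pmax(E, 0), 1)
}

#' Advance one CABARET stage (low-level engine)
#'
#' Generic driver for the seven-sub-stage monotone CABARET scheme.  The
#' physical embolization stage is run through [run_stage()]; this engine also
#' accepts arbitrary flow and inlet closures, which is how the linear
#' advection and Buckley-Leverett verification problems are set up.
#'
#' @param fields a [stage_fields()] with the initial state.
#' @param ff a [fractional_flow()].
#' @param duration local stage duration (s, > 0).
#' @param flow_fun `function(t, Vbar) -> Q` mixture flow (cm^3/s, > 0).
#' @param inlet_fun `function(t_base, t_eval, Vbar) -> f0` inlet flux in
#'   `[0, 1]`; `t_base` is the current layer time `t^n`, `t_eval` the time of
#'   the layer being computed (`t^{n+1/2}` or `t^{n+1}`), `Vbar` the mean
#'   blood fraction at that layer.
#' @param r CFL number in (0, 1].
#' @param breakpoints times (s) the stepping must land on exactly (control
#'   kinks); the stage end is always included.
#' @param pressure_fun optional `function(fields, Q) -> p1` (mmHg) recorded in
#'   the trace; `NA` if omitted.
#' @param extra_speed_fun optional `function(t, Q)` returning an additional
#'   characteristic speed for the CFL bound (see [cfl_timestep()]); used to
#'   account for the fastest wave the inlet can inject into a still-uniform
#'   field.
#' @param max_steps hard cap on the number of time steps.
#' @param record if `FALSE`, the trace keeps only the running extrema (faster).
#' @return `list(fields, trace, steps, max_p1, min_S_outlet)`; `trace` is a
#'   data frame with columns `t, tau, Q, p1, Sbar, S_outlet, tv` (`tau` is
#'   `NA` on the terminal row).
#' @export
cabaret_run <- function(fields, ff, duration, flow_fun, inlet_fun, r = 0.5,
                        breakpoints = numeric(0), pressure_fun = NULL,
                        extra_speed_fun = NULL, max_steps = 500000L,
                        record = TRUE) {
  stopifnot(inherits(fields, "stage_fields"), duration > 0)
  bps <- sort(unique(c(breakpoints[breakpoints > 0 & breakpoints < duration],
                       duration)))
  t <- 0; n <- 0L
  rows <- vector("list", 1024L)
  nrow_used <- 0L
  max_p1 <- -Inf; min_out <- Inf
  push <- function(t, tau, Q, p1, Sbar, S_out, tv) {
    nrow_used <<- nrow_used + 1L
    if (nrow_used > length(rows)) length(rows) <<- 2L * length(rows)
    rows[[nrow_used]] <<- c(t, tau, Q, p1, Sbar, S_out, tv)
  }

  repeat {
    Vbar <- psi_mean(fields)
    Q <- flow_fun(t, Vbar)
    if (!is.finite(Q) || Q <= 0) stop("mixture flow must stay positive")
    p1 <- if (is.null(pressure_fun)) NA_real_ else pressure_fun(fields, Q)
    max_p1 <- max(max_p1, p1, na.rm = TRUE)
    min_out <- min(min_out, fields$u[fields$grid$J + 1L])
    done <- t >= duration - 1e-12
    if (record || done)
      push(t, if (done) NA_real_ else 0, Q, p1, Vbar,
           fields$u[fields$grid$J + 1L], sum(abs(diff(fields$u))))
    if (done) break

    xs <- if (is.null(extra_speed_fun)) 0 else extra_speed_fun(t, Q)
    tau <- cfl_timestep(fields, Q, ff, r, t, bps, extra_speed = xs,
                        tau_floor = duration / CFL_STEP_BUDGET)
    if (record) rows[[nrow_used]][2] <- tau

    U_half <- half_step(fields, Q, tau, ff)
    Vbar_h <- psi_mean(fields, U_half)
    f0_h <- inlet_fun(t, t + tau / 2, Vbar_h)
    f_int <- interior_fluxes(fields, U_half, Q, tau, ff)
    Q_h <- flow_fun(t + tau / 2, Vbar_h)
    U_new <- full_step(fields, c(f0_h, f_int), Q_h, tau)
    U_new <- pmin(pmax(U_new, 0), 1)
    Vbar_1 <- psi_mean(fields, U_new)
    f0_1 <- inlet_fun(t, t + tau, Vbar_1)
    u_new <- flux_variable_update(fields, U_new, f_int, f0_1, ff)
    u_new <- pmin(pmax(u_new, 0), 1)

    fields$u <- u_new
    fields$U <- U_new
    t <- t + tau
    n <- n + 1L
    if (n > max_steps)
      stop(sprintf("step cap exceeded (%d steps); runaway time step", max_steps))
  }

  tr <- do.call(rbind, rows[seq_len(nrow_used)])
  trace <- data.frame(t = tr[, 1], tau = tr[, 2], Q = tr[, 3], p1 = tr[, 4],
                      Sbar = tr[, 5], S_outlet = tr[, 6], tv = tr[, 7])
  list(fields = fields, trace = trace, steps = n,
       max_p1 = if (is.finite(max_p1)) max_p1 else NA_real_,
       min_S_outlet = min_out)
}

#' Run one embolization stage
#'
#' Initializes `u = U = 1` on the stage lumen (only blood at each stage
#' start), builds the injection `q_e(t) = gamma_i Q_i(T_{i-1}) E_i(t)` with
#' the stage-start flow frozen at `Q_i(T_{i-1}) = qbar_b(Psi-bar at start)`,
#' and advances the CABARET scheme over the stage duration, landing exactly
#' on the ramp kinks.  Records flow, inlet pressure, mean blood fraction and
#' outlet saturation at every step.
#'
#' @param model a [patient_model()].
#' @param ff a [fractional_flow()].
#' @param plan a [control_plan()].
#' @param i stage index.
#' @param grid a [grid1d()].
#' @param r CFL number.
#' @param Ai_nodes,Ai_half stage cross-section (defaults to `A1`; supply the
#'   values produced by [link_stage()] for stages `i > 1`).
#' @param max_steps step cap.
#' @param record keep the full per-step trace (default) or only extrema.
#' @param engine `"auto"` (compiled when the model uses the closed-form bed
#'   curves and mobility-ratio flux, reference otherwise), `"compiled"`, or
#'   `"reference"` (the pure-R path through the exported sub-stage
#'   operations).  Both paths implement the identical scheme.
#' @return `list(fields, trace, steps, max_p1, min_S_outlet, Q_start, Psi)`
#'   where `Psi = U A_i / A1` is the terminal blood fraction of the original
#'   cross-section at the half nodes.
#' @export
run_stage <- function(model, ff, plan, i, grid, r = 0.5,
                      Ai_nodes = NULL, Ai_half = NULL,
                      max_steps = 500000L, record = TRUE,
                      engine = c("auto", "compiled", "reference")) {
  stopifnot(inherits(plan, "control_plan"), i >= 1, i <= length(plan$stages))
  engine <- match.arg(engine)
  st <- plan$stages[[i]]
  eps <- plan$epsilon
  D <- st$theta1 + st$theta2 + eps
  fields <- stage_fields(grid, model, Ai_nodes, Ai_half)

  Q_start <- model$qbar_b(min(max(psi_mean(fields), 0), 1))

  compilable <- !is.null(ff$mobility) && !is.null(model$bed)
  if (engine == "compiled" && !compilable)
    stop("compiled engine needs the mobility-ratio flux and bed-curve model family")
  if (engine != "reference" && compilable) {
    g <- grid; mob <- ff$mobility; bed <- model$bed
    out <- .cabaret_stage_cpp(
      J = g$J, h = g$h, L = g$L,
      m_nodes = fields$m_nodes, m_half = fields$m_half,
      Ai_nodes = fields$Ai_nodes, Ai_half = fields$Ai_half,
      A1_nodes = fields$A1_nodes, A1_half = fields$A1_half,
      alpha_b = mob$alpha_b, alpha_e = mob$alpha_e,
      eta_b = mob$eta_b, eta_e = mob$eta_e, K = model$K,
      q_base = bed$q_base, q_floor = bed$q_floor_frac,
      q_shape = bed$q_shape, p_base = bed$p_out_base,
      p_drop = bed$p_out_drop,
      gamma = st$gamma, theta1 = st$theta1, theta2 = st$theta2,
      eps = eps, Qstart = Q_start, df_max = ff$df_max,
      r = r, max_steps = max_steps, record = record)
    fields$u <- out$u
    fields$U <- out$U
    tr <- out$trace
    trace <- data.frame(t = tr[, 1], tau = tr[, 2], Q = tr[, 3], p1 = tr[, 4],
                        Sbar = tr[, 5], S_outlet = tr[, 6], tv = tr[, 7])
    res <- list(fields = fields, trace = trace, steps = out$steps,
                max_p1 = out$max_p1, min_S_outlet = out$min_S_outlet)
    res$Q_start <- Q_start
    res$Psi <- fields$U * fields$Ai_half / fields$A1_half
    res$stage <- i
    return(res)
  }

  qe <- function(s) st$gamma * Q_start * profile_local(st, eps, s)

  res <- cabaret_run(
    fields, ff, duration = D,
    flow_fun = function(t, Vbar) mixture_flow(qe(t), Vbar, model),
    inlet_fun = function(t_base, t_eval, Vbar) {
      qb <- model$qbar_b(min(max(Vbar, 0), 1))
      qb / (qe(t_base) + qb)
    },
    r = r,
    breakpoints = c(st$theta1, D - eps, D),
    pressure_fun = function(flds, Q) discrete_pressure(flds, Q, model, ff),
    extra_speed_fun = if (st$gamma > 0) {
      Ai0 <- max(fields$Ai_nodes[1], CFL_A_FRAC * fields$A1_nodes[1])
      inlet_coef <- ff$df_max / (fields$m_nodes[1] * Ai0)
      function(t, Q) Q * inlet_coef
    },
    max_steps = max_steps, record = record
  )
  res$Q_start <- Q_start
  res$Psi <- res$fields$U * res$fields$Ai_half / res$fields$A1_half
  res$stage <- i
  res
}
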