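# ---- patient configs -------------------------------------------------------

#' Write / read a patient model as a YAML config
#'
#' Serializable patients are those whose response curves come from
#' [bed_curve_params()] (which includes all fixtures and [random_patient()]).
#' Constant `A1`/`m` are stored as scalars; varying profiles are stored as
#' 33-knot piecewise-linear samples and restored with [stats::approxfun()].
#'
#' @param model a [patient_model()] with a `bed` component.
#' @param path file path.
#' @return `write_patient_config`: the path, invisibly.
#' @export
write_patient_config <- function(model, path) {
  stopifnot(inherits(model, "patient_model"))
  if (is.null(model$bed))
    stop("only patients with bed-curve parameters can be serialized")
  ser_fun <- function(f) {
    xs <- seq(0, model$L, length.out = 33L)
    ys <- f(xs)
    if (max(ys) - min(ys) < 1e-12 * max(abs(ys)))
      ys[1]
    else
      list(x = as.numeric(xs), y = as.numeric(ys))
  }
  cfg <- list(patient = list(
    name = model$name, L = model$L,
    A1 = ser_fun(model$A1), m = ser_fun(model$m),
    K = model$K, alpha_b = model$alpha_b,
    eta_b = model$eta_b, eta_e = model$eta_e, p_star = model$p_star,
    bed = unclass(model$bed)
  ))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_patient_config
#' @return `read_patient_config`: a [patient_model()].
#' @export
read_patient_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  p <- cfg$patient %||% cfg
  de_fun <- function(v, name) {
    if (is.list(v)) stats::approxfun(v$x, v$y, rule = 2) else v
  }
  bed <- do.call(bed_curve_params, p$bed)
  curves <- make_bed_curves(bed)
  patient_model(L = p$L, A1 = de_fun(p$A1), m = de_fun(p$m), K = p$K,
                alpha_b = p$alpha_b, eta_b = p$eta_b, eta_e = p$eta_e,
                p_star = p$p_star, qbar_b = curves$qbar_b, p2 = curves$p2,
                bed = bed, name = p$name %||% NULL)
}

# ---- run configs -----------------------------------------------------------

#' Default run configuration
#'
#' The reference numerical setup: `J = 100` cells, CFL `r = 0.5`, ramp-down
#' `epsilon = 0.1` s, penalty weight `R = 1000`, and swarm constants
#' `P = 0.15`, `w1 = 0.9`, `w2 = 0.5`, `c1 = c2 = 1.49`, `I = 300`
#' iterations, with `M = 16` particles for two-stage plans and `M = 32` for
#' three or more stages.
#'
#' @param N number of embolization stages (sets the default particle count).
#' @return A named list of defaults.
#' @export
default_run_config <- function(N = 2L) {
  list(J = 100L, cfl = 0.5, epsilon = 0.1, R = 1000,
       P = 0.15, w1 = 0.9, w2 = 0.5, c1 = 1.49, c2 = 1.49,
       I = 300L, M = if (N >= 3) 32L else 16L,
       gamma_max = 30, theta_max = 10, seed = 1L)
}

# accept a fixture name, a patient config path, a nested spec or a model
resolve_patient <- function(spec) {
  if (inherits(spec, "patient_model")) return(spec)
  if (is.character(spec) && length(spec) == 1L) {
    if (spec %in% names(.fixture_table)) return(patient_fixture(spec))
    if (file.exists(spec)) return(read_patient_config(spec))
    stop(sprintf("unknown patient '%s' (not a fixture name or config file)", spec))
  }
  if (is.list(spec)) {
    tmp <- tempfile(fileext = ".yaml")
    on.exit(unlink(tmp))
    yaml::write_yaml(list(patient = spec), tmp)
    return(read_patient_config(tmp))
  }
  stop("cannot interpret patient specification")
}

#' Load a run configuration
#'
#' Reads a YAML run config (patient, grid, CFL, plan or optimizer settings)
#' and fills unset values from [default_run_config()].
#'
#' @param path YAML file path, or an already-parsed list.
#' @return A list with classes resolved: `patient` ([patient_model()]),
#'   `plan` ([control_plan()] or `NULL`), `optimize` settings, numerics.
#' @export
load_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  N <- if (!is.null(cfg$plan)) length(cfg$plan$stages) else cfg$optimize$N %||% 2L
  def <- default_run_config(N)
  for (k in c("cfl", "epsilon", "R", "seed")) cfg[[k]] <- cfg[[k]] %||% def[[k]]
  cfg$J <- cfg$grid$J %||% cfg$J %||% def$J
  if (is.null(cfg$patient)) stop("run config must name a patient")
  cfg$patient <- resolve_patient(cfg$patient)
  if (!is.null(cfg$plan)) {
    stages <- lapply(cfg$plan$stages, function(s)
      stage_control(s$gamma, s$theta1, s$theta2))
    cfg$plan <- control_plan(stages, epsilon = cfg$epsilon)
  } else if (!is.null(cfg$optimize)) {
    o <- cfg$optimize
    for (k in c("M", "I", "P", "w1", "w2", "c1", "c2", "gamma_max", "theta_max"))
      o[[k]] <- o[[k]] %||% def[[k]]
    o$N <- o$N %||% N
    cfg$optimize <- o
  } else stop("run config must contain either 'plan' or 'optimize'")
  cfg
}

# ---- result serialization --------------------------------------------------

write_stage_outputs <- function(ev, model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- ev$grid
  for (i in seq_along(ev$stages)) {
    s <- ev$stages[[i]]
    utils::write.csv(s$trace[c("t", "tau", "Q", "p1", "Sbar", "S_outlet")],
                     file.path(dir, sprintf("stage_%d_trace.csv", i)),
                     row.names = FALSE)
    flds <- s$fields
    utils::write.csv(data.frame(x = g$x_nodes, u = flds$u),
                     file.path(dir, sprintf("stage_%d_u.csv", i)),
                     row.names = FALSE)
    utils::write.csv(data.frame(x_half = g$x_half, U = flds$U,
                                A_i = flds$Ai_half, Psi = s$Psi),
                     file.path(dir, sprintf("stage_%d_U.csv", i)),
                     row.names = FALSE)
  }
  summary <- list(
    patient = model$name, J = g$J, J_N = ev$J_N, J_hat = ev$J_hat,
    R = ev$R,
    stages = lapply(seq_along(ev$stages), function(i) list(
      I1 = unname(ev$penalties[i, 1]), I2 = unname(ev$penalties[i, 2]),
      max_p1 = ev$stages[[i]]$max_p1,
      min_S_outlet = ev$stages[[i]]$min_S_outlet,
      steps = ev$stages[[i]]$steps
    ))
  )
  yaml::write_yaml(summary, file.path(dir, "summary.yaml"))
  invisible(summary)
}

# ---- CLI entry points ------------------------------------------------------

#' Simulate a configured embolization plan
#'
#' Runs [simulate_plan()] for the plan in a run config and writes per-stage
#' traces, terminal fields and a YAML summary into `output_dir`.
#'
#' @param config path to a YAML run config, or a parsed list.
#' @param output_dir overrides the config's `output_dir`.
#' @return Exit status 0, invisibly; errors propagate as conditions.
#' @export
cmd_simulate <- function(config, output_dir = NULL) {
  cfg <- load_run_config(config)
  if (is.null(cfg$plan)) stop("cmd_simulate() needs a 'plan' in the config")
  dir <- output_dir %||% cfg$output_dir %||% "avmemb-out"
  ev <- simulate_plan(cfg$patient, plan = cfg$plan,
                      grid = grid1d(cfg$patient$L, cfg$J),
                      r = cfg$cfl, R = cfg$R)
  write_stage_outputs(ev, cfg$patient, dir)
  invisible(0L)
}

#' Optimize an embolization plan
#'
#' Runs the particle swarm over `simulate_plan(unpack_plan(x))`, writes the
#' best plan (YAML), the iteration history (CSV), and then re-simulates the
#' best plan with full tracing into `output_dir`.
#'
#' @inheritParams cmd_simulate
#' @return Exit status 0, invisibly.
#' @export
cmd_optimize <- function(config, output_dir = NULL) {
  cfg <- load_run_config(config)
  if (is.null(cfg$optimize)) stop("cmd_optimize() needs an 'optimize' block in the config")
  o <- cfg$optimize
  dir <- output_dir %||% cfg$output_dir %||% "avmemb-out"
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- cfg$patient
  ff <- build_fractional_flow(model)
  grid <- grid1d(model$L, cfg$J)
  obj <- function(x) {
    simulate_plan(model, ff, unpack_plan(x, epsilon = cfg$epsilon),
                  grid = grid, r = cfg$cfl, R = cfg$R, record = FALSE)$J_hat
  }
  sc <- swarm_config(dim = 3L * o$N, M = o$M, I = o$I, P = o$P,
                     w1 = o$w1, w2 = o$w2, c1 = o$c1, c2 = o$c2, R = cfg$R,
                     bounds = control_bounds(o$N, o$gamma_max, o$theta_max),
                     seed = cfg$seed)
  fit <- pso_optimize(sc, obj)
  utils::write.csv(data.frame(iteration = seq_along(fit$history) - 1L,
                              best_value = fit$history),
                   file.path(dir, "history.csv"), row.names = FALSE)
  best <- unpack_plan(fit$par, epsilon = cfg$epsilon)
  yaml::write_yaml(list(
    J_hat = fit$value, epsilon = cfg$epsilon,
    stages = lapply(best$stages, function(s)
      list(gamma = s$gamma, theta1 = s$theta1, theta2 = s$theta2))
  ), file.path(dir, "best_plan.yaml"))
  ev <- simulate_plan(model, ff, best, grid = grid, r = cfg$cfl, R = cfg$R)
  write_stage_outputs(ev, model, dir)
  invisible(0L)
}

#' Write a patient config
#'
#' Thin wrapper over [patient_fixture()] / [random_patient()].
#'
#' @param out output YAML path.
#' @param fixture fixture name (`"K"`, `"S"`, `"P"`), or `NULL`.
#' @param seed seed for a random synthetic patient (used when `fixture` is
#'   `NULL`).
#' @param ... forwarded to [random_patient()].
#' @return Exit status 0, invisibly.
#' @export
cmd_make_patient <- function(out, fixture = NULL, seed = NULL, ...) {
  model <- if (!is.null(fixture)) patient_fixture(fixture)
  else if (!is.null(seed)) random_patient(seed, ...)
  else stop("provide either a fixture name or a seed")
  write_patient_config(model, out)
  invisible(0L)
}
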