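# shared fixtures: a unit-geometry model for scheme verification problems and
# small helpers to run the generic engine on them

unit_model <- function(alpha_b = 2) {
  patient_model(L = 1, A1 = 1, m = 1, K = 1, alpha_b = alpha_b,
                eta_b = 0.04, eta_e = 0.18, p_star = 1e9,
                qbar_b = function(S) rep(1, length(S)),
                p2 = function(S) rep(0, length(S)))
}

linear_ff <- function() {
  fractional_flow(function(S) S, function(S) rep(1, length(S)), name = "linear")
}

# mobility-ratio flux with quadratic permeabilities, blood 4 cP / agent 18 cP
quad_mobility_ff <- function() {
  build_fractional_flow(unit_model(alpha_b = 2), alpha_e = 2)
}

# pure-displacement Riemann run: constant Q = m = A = 1, inlet state S = 0
riemann_run <- function(J, ff, duration, r = 0.5, record = TRUE) {
  g <- grid1d(1, J)
  flds <- stage_fields(g, unit_model())
  res <- cabaret_run(flds, ff, duration = duration,
                     flow_fun = function(t, V) 1,
                     inlet_fun = function(tb, te, V) 0,
                     r = r,
                     extra_speed_fun = function(t, Q) Q * ff$df_max,
                     max_steps = 200000L, record = record)
  res$grid <- g
  res
}

# locate the shock in a monotone numerical profile by linear interpolation of
# the crossing of the mid-value between the tangent state and the right state
shock_position <- function(u, x, s_tangent, SR = 1) {
  um <- 0.5 * (s_tangent + SR)
  i <- which(u >= um)[1]
  x[i - 1] + (um - u[i - 1]) / (u[i] - u[i - 1]) * (x[i] - x[i - 1])
}
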