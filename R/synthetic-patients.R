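#' Parameters of the synthetic healthy-bed response curves
#'
#' The clinical response of the healthy vascular bed — blood inflow
#' `qbar_b(Sbar)` into the AVM and outlet pressure `p2(Sbar)` — is only ever
#' measured per patient; here it is emulated by a smooth two-parameter family.
#' `qbar_b` must be strictly positive (some blood always reaches the AVM) and
#' increasing in the mean blood fraction `Sbar`; `p2` is smooth and bounded.
#'
#' @param q_base inflow at `Sbar = 1` (cm^3/s), i.e. the pre-operative blood
#'   flow through the AVM.
#' @param q_floor_frac fraction of `q_base` remaining at `Sbar = 0`, in (0,1).
#' @param q_shape curvature exponent (>= 1) of the inflow curve.
#' @param p_out_base outlet pressure at `Sbar = 1` (mmHg).
#' @param p_out_drop pressure change from `Sbar = 1` down to `Sbar = 0` (mmHg).
#' @return An object of class `bed_curve_params`.
#' @export
bed_curve_params <- function(q_base = 0.35, q_floor_frac = 0.15, q_shape = 2,
                             p_out_base = 20, p_out_drop = 8) {
  stopifnot(q_base > 0, q_floor_frac > 0, q_floor_frac < 1, q_shape >= 1)
  structure(list(q_base = q_base, q_floor_frac = q_floor_frac,
                 q_shape = q_shape, p_out_base = p_out_base,
                 p_out_drop = p_out_drop),
            class = "bed_curve_params")
}

#' Build healthy-bed response functions
#'
#' Returns the pair of scalar functions
#' `qbar_b(Sbar) = q_base * (q_floor_frac + (1 - q_floor_frac) * Sbar^q_shape)`
#' and `p2(Sbar) = p_out_base - p_out_drop * (1 - Sbar)`.
#' `qbar_b` is smooth, strictly increasing and strictly positive on `[0, 1]`;
#' `p2` is affine and bounded.
#'
#' @param params a [bed_curve_params()].
#' @return `list(qbar_b = <function>, p2 = <function>)`.
#' @export
make_bed_curves <- function(params = bed_curve_params()) {
  stopifnot(inherits(params, "bed_curve_params"))
  qb <- params$q_base; qf <- params$q_floor_frac; qs <- params$q_shape
  pb <- params$p_out_base; pd <- params$p_out_drop
  list(
    qbar_b = function(Sbar) qb * (qf + (1 - qf) * Sbar^qs),
    p2 = function(Sbar) pb - pd * (1 - Sbar)
  )
}

# geometry/filtration characteristics of the three clinical AVM fixtures
.fixture_table <- list(
  K = list(L = 2.4, A = 2.275, K = 7.35e-7, alpha_b = 1.178, p_star = 80.7),
  S = list(L = 3.0, A = 1.327, K = 8.35e-6, alpha_b = 1.380, p_star = 114.6),
  P = list(L = 4.5, A = 4.714, K = 7.94e-6, alpha_b = 1.168, p_star = 55.0)
)

#' Clinical AVM fixtures
#'
#' The three reconstructed racemic-AVM compartments (`"K"`, `"S"`, `"P"`)
#' with their measured geometry and filtration characteristics, combined with
#' synthetic healthy-bed response curves (the measured curves exist only as
#' per-patient graphs).  Viscosities are blood 4 cP and ONYX18 agent 18 cP;
#' porosity is 1 (other constant porosities rescale time) and the
#' cross-section is the constant pre-operative average.
#'
#' @param name `"K"`, `"S"` or `"P"`.
#' @param bed a [bed_curve_params()] for the synthetic response curves.
#' @return A [patient_model()].
#' @export
patient_fixture <- function(name = c("K", "S", "P"), bed = bed_curve_params()) {
  name <- match.arg(name)
  row <- .fixture_table[[name]]
  curves <- make_bed_curves(bed)
  patient_model(
    L = row$L, A1 = row$A, m = 1, K = row$K, alpha_b = row$alpha_b,
    eta_b = 0.04, eta_e = 0.18, p_star = row$p_star,
    qbar_b = curves$qbar_b, p2 = curves$p2, bed = bed, name = name
  )
}

#' Random synthetic patient
#'
#' Draws a patient whose magnitudes bracket the clinical fixtures; optionally
#' with smoothly varying cross-section `A(x)` and porosity `m(x)` (the solver
#' supports both).  Deterministic given `seed`.
#'
#' @param seed integer seed.
#' @param ranges named list of 2-vectors overriding the default sampling
#'   ranges for `L` (cm), `A` (cm^2), `logK` (log10 cm^2), `alpha_b`,
#'   `p_star` (mmHg).
#' @param variable_geometry if `TRUE`, `A(x)` and `m(x)` get a smooth cosine
#'   modulation instead of being constant.
#' @param bed a [bed_curve_params()]; its `q_base` is rescaled by the drawn
#'   cross-section so inflow magnitudes stay physiological.
#' @return A [patient_model()].
#' @export
random_patient <- function(seed, ranges = list(), variable_geometry = FALSE,
                           bed = bed_curve_params()) {
  def <- list(L = c(2, 5), A = c(1.2, 5), logK = c(-6.2, -5.0),
              alpha_b = c(1.1, 1.5), p_star = c(55, 115))
  def[names(ranges)] <- ranges
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  rdraw <- function(r) stats::runif(1, r[1], r[2])
  L <- rdraw(def$L); A <- rdraw(def$A); K <- 10^rdraw(def$logK)
  alpha_b <- rdraw(def$alpha_b); p_star <- rdraw(def$p_star)

  if (variable_geometry) {
    ampA <- stats::runif(1, 0.05, 0.25)
    ampm <- stats::runif(1, 0.0, 0.15)
    phase <- stats::runif(1, 0, 2 * pi)
    A1 <- function(x) A * (1 + ampA * cos(2 * pi * x / L + phase))
    m <- function(x) 1 - ampm * (0.5 + 0.5 * sin(2 * pi * x / L))
  } else {
    A1 <- A
    m <- 1
  }
  # scale pre-op inflow with lumen area; keep outlet pressure below p_star
  bed$q_base <- bed$q_base * A / 2.275
  bed$p_out_base <- min(bed$p_out_base, 0.6 * p_star)
  curves <- make_bed_curves(bed)
  patient_model(L = L, A1 = A1, m = m, K = K, alpha_b = alpha_b,
                eta_b = 0.04, eta_e = 0.18, p_star = p_star,
                qbar_b = curves$qbar_b, p2 = curves$p2, bed = bed,
                name = sprintf("synthetic-%d", as.integer(seed)))
}
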