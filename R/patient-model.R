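#' Patient model of an AVM compartment
#'
#' Bundles everything the filtration model needs about one patient: geometry
#' (length `L`, initial cross-section `A1(x)`), porosity `m(x)`, absolute
#' permeability `K`, the power-law relative permeability of blood
#' `k_b(S) = S^alpha_b`, phase viscosities, the critical inlet pressure
#' `p_star`, and the two healthy-bed response curves: blood inflow
#' `qbar_b(Sbar)` and outlet pressure `p2(Sbar)` as functions of the mean
#' blood fraction in the AVM.
#'
#' @param L AVM length (cm), positive.
#' @param A1 initial cross-section area (cm^2); a positive constant or a
#'   function of `x` on `[0, L]`.
#' @param m porosity; a constant in `(0, 1]` or a function of `x`.
#' @param K absolute permeability (cm^2), positive.
#' @param alpha_b exponent of the blood relative permeability
#'   `k_b(S) = S^alpha_b`, positive.
#' @param eta_b,eta_e blood and embolic agent viscosities (poise;
#'   1 cP = 0.01 poise).
#' @param p_star critical inlet pressure (mmHg).
#' @param qbar_b function `Sbar -> cm^3/s`, strictly positive on `[0, 1]`
#'   (guarantees `Q(t) > 0` so all characteristics run left to right).
#' @param p2 function `Sbar -> mmHg`, outlet pressure.
#' @param bed optional [bed_curve_params()] the response curves were built
#'   from; kept for serialization.
#' @param name optional label.
#'
#' @return An object of class `patient_model`.
#' @seealso [patient_fixture()], [make_bed_curves()], [build_fractional_flow()]
#' @export
patient_model <- function(L, A1, m, K, alpha_b, eta_b, eta_e, p_star,
                          qbar_b, p2, bed = NULL, name = NULL) {
  stopifnot(is.numeric(L), length(L) == 1L, L > 0,
            is.numeric(K), length(K) == 1L, K > 0,
            is.numeric(alpha_b), length(alpha_b) == 1L, alpha_b > 0,
            is.numeric(eta_b), eta_b > 0, is.numeric(eta_e), eta_e > 0,
            is.numeric(p_star), length(p_star) == 1L,
            is.function(qbar_b), is.function(p2))
  A1 <- as_xfun(A1, "A1")
  m <- as_xfun(m, "m")

  xs <- seq(0, L, length.out = 101L)
  if (any(A1(xs) <= 0)) stop("A1(x) must be positive on [0, L]")
  mv <- m(xs)
  if (any(mv <= 0 | mv > 1)) stop("m(x) must lie in (0, 1] on [0, L]")
  ss <- seq(0, 1, length.out = 101L)
  if (any(qbar_b(ss) <= 0)) stop("qbar_b(Sbar) must be strictly positive on [0, 1]")
  if (any(!is.finite(p2(ss)))) stop("p2(Sbar) must be finite on [0, 1]")

  force(alpha_b)
  obj <- list(
    L = L, A1 = A1, m = m, K = K, alpha_b = alpha_b,
    eta_b = eta_b, eta_e = eta_e, p_star = p_star,
    qbar_b = qbar_b, p2 = p2,
    kb = function(S) S^alpha_b,
    bed = bed, name = name
  )
  class(obj) <- "patient_model"
  obj
}

#' @export
print.patient_model <- function(x, ...) {
  cat("<patient_model", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat(sprintf("  L = %g cm, K = %g cm^2, k_b(S) = S^%g, p* = %g mmHg\n",
              x$L, x$K, x$alpha_b, x$p_star))
  cat(sprintf("  A1(0) = %g cm^2, m(0) = %g, eta_b = %g P, eta_e = %g P\n",
              x$A1(0), x$m(0), x$eta_b, x$eta_e))
  cat(sprintf("  qbar_b(1) = %g cm^3/s, p2(1) = %g mmHg\n",
              x$qbar_b(1), x$p2(1)))
  invisible(x)
}

#' Local resistance to blood flow inside the AVM
#'
#' Darcy resistance per unit length,
#' `r_b = eta_b / (A(x) * K * k_b(S))` (CGS units).  Diverges as `S -> 0`;
#' the pressure quadrature guards that limit through the `f/k_b` ratio rule,
#' see [discrete_pressure()].
#'
#' @param model a [patient_model()].
#' @param x position (cm) in `[0, L]`.
#' @param S blood saturation in `(0, 1]`.
#' @return Resistance per unit length (CGS).
#' @export
blood_resistance <- function(model, x, S) {
  if (any(S <= 0)) stop("blood_resistance() requires S > 0")
  model$eta_b / (model$A1(x) * model$K * model$kb(S))
}
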