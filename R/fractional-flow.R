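#' Construct a fractional-flow (Buckley-Leverett) object
#'
#' Low-level constructor from an arbitrary flux function.  `f` must map
#' `[0, 1]` onto `[0, 1]` and be strictly increasing; the numerical inverse is
#' a safeguarded bisection on `[0, 1]` and the inflection point `xi` (if any)
#' is located by a sign-change scan of second differences on a dense grid.
#'
#' Mainly useful for test fluxes such as `f(S) = S`; the physical mobility
#' ratio flux is built by [build_fractional_flow()].
#'
#' @param f flux function on `[0, 1]`.
#' @param df its derivative; if `NULL`, a central-difference approximation is
#'   used.
#' @param name optional label.
#' @param n_check number of grid points used to verify monotonicity and to
#'   scan for the inflection.
#' @return An object of class `fractional_flow` with elements `f`, `df`,
#'   `finv`, `xi` (or `NA` if no inflection).
#' @export
fractional_flow <- function(f, df = NULL, name = NULL, n_check = 2001L) {
  stopifnot(is.function(f))
  if (abs(f(0)) > 1e-12 || abs(f(1) - 1) > 1e-12)
    stop("flux must satisfy f(0) = 0 and f(1) = 1")
  s <- seq(0, 1, length.out = n_check)
  fs <- f(s)
  if (any(diff(fs) <= 0))
    stop("flux must be strictly increasing on [0, 1]")
  if (is.null(df)) {
    eps <- 1e-6
    df <- function(S) {
      lo <- pmax(S - eps, 0); hi <- pmin(S + eps, 1)
      (f(hi) - f(lo)) / (hi - lo)
    }
  }
  d2 <- diff(fs, differences = 2L)
  sgn <- sign(d2[abs(d2) > 1e-13 * max(abs(d2), 1e-300)])
  xi <- NA_real_
  if (length(sgn) > 1L && any(diff(sgn) != 0)) {
    k <- which(diff(sgn) != 0)[1L]
    # map back to the s-location of the sign change
    idx <- which(abs(d2) > 1e-13 * max(abs(d2), 1e-300))
    xi <- s[idx[k] + 1L]
  }
  obj <- list(f = f, df = df, finv = NULL, xi = xi, name = name,
              df_max = max(df(s)))
  obj$finv <- function(y) .ff_bisect(f, y)
  class(obj) <- "fractional_flow"
  obj
}

# vectorized safeguarded bisection of a strictly increasing f on [0, 1]
.ff_bisect <- function(f, y, tol = 1e-13, maxit = 60L) {
  if (any(y < -1e-12 | y > 1 + 1e-12))
    stop("fractional flow inverse requested outside [0, 1]")
  y <- pmin(pmax(y, 0), 1)
  lo <- rep.int(0, length(y)); hi <- rep.int(1, length(y))
  for (it in seq_len(maxit)) {
    mid <- 0.5 * (lo + hi)
    below <- f(mid) < y
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
    if (max(hi - lo) < tol) break
  }
  mid <- 0.5 * (lo + hi)
  # pin the exact endpoints
  mid[y <= 0] <- 0
  mid[y >= 1] <- 1
  mid
}

#' @export
print.fractional_flow <- function(x, ...) {
  cat("<fractional_flow", if (!is.null(x$name)) paste0("'", x$name, "'"), ">\n")
  cat(sprintf("  f(0.5) = %.6f, inflection xi = %s\n", x$f(0.5),
              if (is.na(x$xi)) "none" else format(x$xi, digits = 4)))
  invisible(x)
}

#' Mobility-ratio fractional flow for a patient
#'
#' The classical two-phase fractional flow of the displaced phase (blood),
#' \deqn{f(S) = \frac{k_b(S)/\eta_b}{k_b(S)/\eta_b + k_e(1-S)/\eta_e},}
#' with power-law relative permeabilities `k_b(S) = S^alpha_b` (from the
#' patient model) and `k_e(x) = x^alpha_e` for the embolic agent.  With real
#' viscosities (blood 4 cP, agent 18 cP) and exponents above 1 this is the
#' S-shaped Buckley-Leverett flux with a single inflection.
#'
#' @param model a [patient_model()].
#' @param alpha_e embolic-phase relative permeability exponent (>= 1); the
#'   clinical reconstruction only pins down `k_b`, so `alpha_e` is a free
#'   modeling parameter (default 2).
#' @return A [fractional_flow()] object with an analytic derivative.
#' @export
build_fractional_flow <- function(model, alpha_e = 2) {
  stopifnot(inherits(model, "patient_model"), alpha_e >= 1)
  a <- model$alpha_b; b <- alpha_e
  eb <- model$eta_b; ee <- model$eta_e
  f <- function(S) {
    lb <- S^a / eb
    le <- (1 - S)^b / ee
    lb / (lb + le)
  }
  df <- function(S) {
    lb <- S^a / eb
    le <- (1 - S)^b / ee
    dlb <- a * S^(a - 1) / eb
    dle <- -b * (1 - S)^(b - 1) / ee
    (dlb * le - lb * dle) / (lb + le)^2
  }
  ff <- fractional_flow(f, df, name = sprintf("mobility-ratio a_b=%g a_e=%g", a, b))
  # parameters of the closed-form family; their presence enables the
  # compiled stage engine, which re-evaluates f, f' and f^-1 natively
  ff$mobility <- list(alpha_b = a, alpha_e = b, eta_b = eb, eta_e = ee)
  ff
}

#' Invert a fractional flow value
#'
#' Solves `f(S) = y` for `S` in `[0, 1]` by safeguarded bisection (the flux is
#' strictly increasing), to within `1e-12`.
#'
#' @param ff a [fractional_flow()].
#' @param y value(s) in `[0, 1]` (tolerance `1e-12` outside).
#' @return Saturation(s) in `[0, 1]`.
#' @export
fractional_flow_invert <- function(ff, y) {
  stopifnot(inherits(ff, "fractional_flow"))
  ff$finv(y)
}

#' Check the Buckley-Leverett shape conditions
#'
#' Verifies on a dense grid that `f(0) = 0`, `f(1) = 1`, `f' > 0` on `(0, 1)`,
#' and that `f''` changes sign exactly once from positive (convex near 0) to
#' negative (concave near 1).  Failures are reported, not raised, so linear
#' and convex test fluxes remain usable with the solver.
#'
#' @param ff a [fractional_flow()].
#' @param n grid size for the scan.
#' @return A data frame with columns `condition`, `pass`; attribute `xi`
#'   carries the located inflection (or `NA`).
#' @export
validate_bl_shape <- function(ff, n = 4001L) {
  stopifnot(inherits(ff, "fractional_flow"))
  s <- seq(0, 1, length.out = n)
  fs <- ff$f(s)
  d2 <- diff(fs, differences = 2L)
  keep <- abs(d2) > 1e-11 * max(abs(d2), 1e-300)
  sgn <- sign(d2[keep])
  runs <- rle(sgn)$values
  one_switch <- identical(runs, c(1, -1))
  out <- data.frame(
    condition = c("f(0) = 0", "f(1) = 1", "f increasing on (0,1)",
                  "single convex-to-concave switch of f''"),
    pass = c(abs(fs[1]) <= 1e-10,
             abs(fs[n] - 1) <= 1e-10,
             all(diff(fs) > 0),
             isTRUE(one_switch))
  )
  if (!all(out$pass))
    warning("fractional flow does not satisfy all Buckley-Leverett shape conditions")
  attr(out, "xi") <- ff$xi
  out
}
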