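#' Analytic Buckley-Leverett Riemann solution (Welge construction)
#'
#' Self-similar solution of `S_t + c f(S)_x = 0` for the displacement Riemann
#' problem: inlet state `SL` (injected agent-rich mixture) against initial
#' state `SR = 1` (pure blood), `SL < SR`, with an S-shaped flux.  The lower
#' convex envelope of `f` on `[SL, SR]` yields a rarefaction from `SL` up to
#' the Welge tangent point `s1` (where `f'(s1) = (f(SR) - f(s1))/(SR - s1)`)
#' followed by a shock from `s1` to `SR` moving at speed `c f'(s1)`.
#'
#' This is the independent reference used to verify the CABARET solver; it
#' never touches the finite-difference path.
#'
#' @param ff a [fractional_flow()] with one inflection (see
#'   [validate_bl_shape()]).
#' @param SL,SR left (inlet) and right (initial) states, `0 <= SL < SR <= 1`.
#' @param c transport coefficient `Q/(m A)` (1/s times cm, i.e. cm/s here).
#' @return List with `s_tangent`, `shock_speed` (`c f'(s1)`), and
#'   `profile(x, t)` returning the exact saturation.
#' @export
bl_riemann_solution <- function(ff, SL = 0, SR = 1, c = 1) {
  stopifnot(SL >= 0, SR <= 1, SL < SR, c > 0)
  xi <- ff$xi
  if (is.na(xi)) stop("flux has no inflection; Welge construction needs an S-shaped flux")
  gfun <- function(s) ff$df(s) * (SR - s) - (ff$f(SR) - ff$f(s))
  # root below the inflection: g < 0 near SL (slope too small), > 0 at xi
  lo <- SL + 1e-9
  if (gfun(lo) >= 0 || gfun(xi) <= 0)
    stop("could not bracket the Welge tangent point")
  s1 <- stats::uniroot(gfun, c(lo, xi), tol = 1e-14)$root
  sigma <- ff$df(s1)          # similarity speed of the shock (before c)

  # invert f' on [SL, s1] (f' increasing there) by bisection
  dfinv <- function(y) {
    lo <- rep.int(SL, length(y)); hi <- rep.int(s1, length(y))
    for (k in 1:60) {
      mid <- 0.5 * (lo + hi)
      below <- ff$df(mid) < y
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    0.5 * (lo + hi)
  }

  profile <- function(x, t) {
    stopifnot(t > 0)
    y <- x / (c * t)
    S <- numeric(length(y))
    S[y <= ff$df(SL)] <- SL
    fan <- y > ff$df(SL) & y < sigma
    S[fan] <- dfinv(y[fan])
    S[y >= sigma] <- SR
    S
  }
  list(s_tangent = s1, shock_speed = c * sigma, profile = profile,
       SL = SL, SR = SR, c = c)
}
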