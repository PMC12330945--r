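#' Equilibrium unfolding curve
#'
#' Evaluates the three-parameter equilibrium unfolding model
#' \deqn{f(T) = \frac{1 - p}{1 + e^{-a (T - b)}} + p}
#' giving the fraction of protein remaining folded at temperature \code{T}.
#' With a negative slope \code{a} the curve decreases from an upper
#' asymptote of 1 (fully folded) to a lower plateau \code{p}
#' (heat-resistant residual signal) as the temperature rises through the
#' inflection point \code{b}.
#'
#' Evaluation goes through \code{\link[stats]{plogis}} and is therefore
#' overflow-safe for arbitrarily large \code{|a (T - b)|}.
#'
#' @param temperature numeric vector of temperatures (degrees Celsius).
#' @param a slope parameter (per degree Celsius). Denaturation curves have
#'   \code{a < 0}; the function itself accepts any finite value.
#' @param b inflection temperature (degrees Celsius).
#' @param p lower plateau, dimensionless fraction.
#' @return numeric vector of fractions folded, same length as
#'   \code{temperature}.
#' @examples
#' eval_unfolding(52, a = -0.5, b = 50, p = 0.2)  # 0.415153
#' eval_unfolding(50, a = -0.8, b = 50, p = 0.1)  # (1 + p) / 2 at T = b
#' @seealso [melting_point()] for the f = 0.5 crossing, [fit_unfolding()]
#'   for estimating the parameters from data.
#' @export
eval_unfolding <- function(temperature, a, b, p) {
  if (!all(is.finite(temperature)) || !all(is.finite(a)) ||
      !all(is.finite(b)) || !all(is.finite(p))) {
    stop("eval_unfolding: all inputs must be finite", call. = FALSE)
  }
  (1 - p) * stats::plogis(a * (temperature - b)) + p
}

#' Melting point of an unfolding curve
#'
#' The melting point Tm (often written Tm50) is the temperature at which
#' half of the protein is denatured, i.e. the solution of
#' \eqn{f(T) = 0.5} for the curve of [eval_unfolding()]. For \code{p < 0.5}
#' it has the closed form
#' \deqn{T_m = b - \log\left(\frac{0.5}{0.5 - p}\right) / a .}
#' When the plateau is at or above 0.5 the curve never reaches 50%
#' denaturation and the melting point is undefined (\code{NA}).
#'
#' @param a slope parameter, must be negative (denaturation with
#'   temperature).
#' @param b inflection temperature (degrees Celsius).
#' @param p lower plateau in \code{[0, 1)}.
#' @return melting temperature in degrees Celsius, or \code{NA_real_} when
#'   \code{p >= 0.5}.
#' @examples
#' melting_point(a = -0.5, b = 50, p = 0)    # b exactly
#' melting_point(a = -0.5, b = 50, p = 0.2)  # 51.0217
#' melting_point(a = -0.5, b = 50, p = 0.5)  # NA: no 0.5 crossing
#' @export
melting_point <- function(a, b, p) {
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(p))) {
    stop("melting_point: parameters must be finite", call. = FALSE)
  }
  if (any(a >= 0)) {
    stop("melting_point: slope `a` must be negative", call. = FALSE)
  }
  n <- max(length(a), length(b), length(p))
  a <- rep_len(a, n); b <- rep_len(b, n); p <- rep_len(p, n)
  tm <- rep(NA_real_, n)
  ok <- p < 0.5
  tm[ok] <- b[ok] - log(0.5 / (0.5 - p[ok])) / a[ok]
  tm
}

# Normalized melting curve: f(T) / f(T_ref). This is the quantity the data
# actually constrain once each replicate is divided by its lowest-temperature
# intensity -- the reference point is exactly 1 by construction, so the model
# must be too.
unfolding_rel <- function(temperature, a, b, p, t_ref) {
  eval_unfolding(temperature, a, b, p) / eval_unfolding(t_ref, a, b, p)
}
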