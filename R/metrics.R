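#' Synchrony summary of a phase-difference density
#'
#' The order parameter is the modulus of the first circular moment,
#' `OP = sqrt(C^2 + S^2)` with `C = integral R(phi) cos(phi) dphi` and
#' `S = integral R(phi) sin(phi) dphi`; it is 0 for a flat density
#' (asynchrony) and 1 for a delta function (perfect locking). The peak
#' position is reported as the angle of the resultant vector `(C, S)`,
#' `atan2(S, C)`, which is robust to binning noise (unlike the argmax
#' bin). The circular variance is `1 - OP`. Quadrature is the periodic
#' trapezoid rule on the density grid, which is spectrally accurate for
#' smooth periodic integrands.
#'
#' @param density a [phase_density()] (or data frame with `phi`,
#'   `density` on a uniform grid over a full period); must be normalized
#' @return a one-row tibble: `OP`, `peak_angle`, `circular_variance`,
#'   `provenance`
#' @examples
#' d <- phase_density(seq(-pi, pi, length.out = 101)[-101] + pi / 100,
#'                    rep(1 / (2 * pi), 100), "closed_form")
#' order_parameter(d)
#' @export
order_parameter <- function(density) {
  if (!all(c("phi", "density") %in% names(density)))
    stop("expected columns phi and density")
  w <- 2 * pi / nrow(density)
  tot <- sum(density$density) * w
  if (abs(tot - 1) > 1e-6)
    stop("density is not normalized (integral = ", signif(tot, 8), ")")
  C <- sum(density$density * cos(density$phi)) * w
  S <- sum(density$density * sin(density$phi)) * w
  OP <- sqrt(C^2 + S^2)
  tibble::tibble(
    OP = OP,
    peak_angle = atan2(S, C),
    circular_variance = 1 - OP,
    provenance = attr(density, "provenance") %||% NA_character_)
}

#' Spike-time cross-correlation implied by a phase-difference density
#'
#' `CC(s) = (R(-s) - 1/(2*pi)) / (2*pi)`: the cross-correlogram of the
#' spike times of two weakly noisy oscillators. A uniform density gives
#' the zero function; a symmetric density peaked at 0 gives a
#' cross-correlation maximal at zero lag with value
#' `(R(0) - 1/(2*pi))/(2*pi)`; heterogeneous pairs give correlograms that
#' peak off-center.
#'
#' @param density a [phase_density()]
#' @return tibble with columns `lag`, `cc`
#' @export
crosscorrelation <- function(density) {
  lag <- density$phi
  cc <- (density_interp(density, -lag) - 1 / (2 * pi)) / (2 * pi)
  tibble::tibble(lag = lag, cc = cc)
}

#' Susceptibility of a homogeneous oscillator pair
#'
#' At small input correlation the zero-lag spike-time cross-correlation
#' of a homogeneous pair is linear in the input correlation, `CC = c*S`,
#' with susceptibility
#' `S = (1/(2*pi)) * (1 - (1/(2*pi)) * integral g(phi)/g(0) dphi)` where
#' `g` is the OU-filtered PRC autocorrelation. Because the mean of `g` is
#' proportional to the squared DC component of the PRC, susceptibility is
#' maximized by minimizing the PRC's DC component; for the
#' exponential-sine family at fixed `C` the optimum is at
#' `a = -arctan(C)`.
#'
#' @param prc a `prc_spec`
#' @param tau OU time constant
#' @return scalar susceptibility
#' @export
susceptibility <- function(prc, tau) {
  g <- filtered_correlation(prc, prc, tau)
  g0 <- g$values[1]
  if (g0 <= 0) stop("g(0) <= 0: susceptibility needs a nonzero PRC")
  (1 / (2 * pi)) * (1 - mean(g$values) / g0)
}
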