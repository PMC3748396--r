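#' Periodic function on a uniform phase grid
#'
#' A light container for real 2*pi-periodic functions sampled on a uniform
#' half-open grid over `[0, 2*pi)`, together with their Fourier coefficients.
#' These carry the PRC cross-correlations `h[nm](phi)` and their
#' noise-filtered versions `g[nm](phi)` between modules.
#'
#' @param values numeric vector of samples on the uniform grid
#'   `phi_j = 2*pi*j/n`, `j = 0, ..., n-1`. `n` must be a power of two and
#'   at least 64, so that truncation error in the spectral operations is
#'   negligible for the smooth functions handled here.
#' @return An object of class `periodic_fn` with fields `values`, `n`,
#'   `grid` and complex Fourier coefficients `coef` (`coef[k]` multiplies
#'   `exp(1i*k*phi)`, stored in FFT order).
#' @examples
#' f <- periodic_fn(cos(seq(0, 2 * pi, length.out = 129)[1:128]))
#' pf_eval(f, pi / 3)
#' @export
periodic_fn <- function(values) {
  n <- length(values)
  if (n < 64 || bitwAnd(n, n - 1L) != 0L)
    stop("grid size must be a power of two >= 64, got ", n)
  if (!all(is.finite(values))) stop("non-finite values in periodic function")
  co <- stats::fft(values) / n
  structure(
    list(values = as.numeric(values), n = n,
         grid = 2 * pi * (seq_len(n) - 1) / n, coef = co),
    class = "periodic_fn"
  )
}

#' @export
print.periodic_fn <- function(x, ...) {
  cat("<periodic_fn> on", x$n, "points; range [",
      signif(min(x$values), 4), ",", signif(max(x$values), 4), "]\n")
  invisible(x)
}

# Signed harmonic numbers in FFT storage order: 0, 1, ..., n/2, -n/2+1, ..., -1
pf_harmonics <- function(n) {
  k <- c(0:(n / 2), (-n / 2 + 1):-1)
  k
}

#' Evaluate a periodic function by trigonometric interpolation
#'
#' @param pf a [periodic_fn()]
#' @param phi numeric vector of phases (any real values; evaluation is
#'   2*pi-periodic)
#' @return numeric vector of function values
#' @export
pf_eval <- function(pf, phi) {
  stopifnot(inherits(pf, "periodic_fn"))
  k <- pf_harmonics(pf$n)
  # treat the unmatched Nyquist mode as a pure cosine
  co <- pf$coef
  ny <- which(k == pf$n / 2)
  vapply(phi, function(p) {
    e <- exp(1i * k * p)
    e[ny] <- cos(k[ny] * p)
    Re(sum(co * e))
  }, numeric(1))
}

#' Cosine/sine coefficients of a periodic function
#'
#' Returns the expansion `a0 + sum_k a_k cos(k phi) + b_k sin(k phi)`.
#'
#' @param pf a [periodic_fn()]
#' @return list with `a0`, vectors `a`, `b` for harmonics `1 .. n/2 - 1`
#' @export
pf_coefs <- function(pf) {
  n <- pf$n
  kk <- 1:(n / 2 - 1)
  list(a0 = Re(pf$coef[1]),
       a = 2 * Re(pf$coef[kk + 1]),
       b = -2 * Im(pf$coef[kk + 1]))
}

# Multiply harmonic k by an arbitrary gain gain(k >= 0); used for the OU
# low-pass filter 1 / (1 + k^2 tau^2).
pf_apply_gain <- function(pf, gain) {
  k <- abs(pf_harmonics(pf$n))
  co <- pf$coef * gain(k)
  periodic_fn(Re(stats::fft(co, inverse = TRUE)))
}

# Spectral derivative d/dphi on the grid.
pf_deriv_values <- function(values) {
  n <- length(values)
  k <- pf_harmonics(n)
  k[k == n / 2] <- 0 # drop the unmatched Nyquist mode from the derivative
  Re(stats::fft(1i * k * stats::fft(values) / n, inverse = TRUE))
}

#' @export
as.data.frame.periodic_fn <- function(x, ...) {
  data.frame(phi = x$grid, value = x$values)
}
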