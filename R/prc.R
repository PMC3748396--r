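#' Phase-response curves
#'
#' A phase-response curve (PRC) `Delta(theta)` gives the shift in the timing
#' of an oscillator's next spike caused by a small perturbation arriving at
#' phase `theta`, with the period normalized to `2*pi` and the spike at phase
#' 0. `corrsync` supports two parametric families and tabulated curves:
#'
#' * **double sinusoidal**: `Delta(theta) = sin(a) - sin(theta + a) +
#'   b*sin(2*theta)`. Its DC component is `sin(a)` and `Delta(0) = 0`.
#' * **exponential sine**: `Delta(x) = scale * (sin(a) - sin(x + a)) *
#'   exp(C*(x - 2*pi))` on `x` in `[0, 2*pi)`, extended by wrapping; for
#'   `C != 0` the periodic extension has a jump at 0. This family is used as
#'   a fitting model for experimentally estimated PRCs.
#' * **tabulated**: at least 16 strictly increasing phase samples spanning
#'   `[0, 2*pi)`, interpolated with a periodic cubic spline.
#'
#' @param a rotation parameter, radians; sets the DC component `sin(a)`
#' @param b second-harmonic amplitude (dimensionless)
#' @return An object of class `prc_spec`.
#' @examples
#' p <- prc_double_sine(0.1, 0.32)
#' prc_eval(p, c(0, pi / 2, pi))
#' dc_component(p)
#' @export
prc_double_sine <- function(a, b) {
  for (nm in c("a", "b")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a finite number")
  }
  new_prc("double_sine", params = list(a = a, b = b))
}

#' @rdname prc_double_sine
#' @param C exponential decay rate (1/rad) of the exponential-sine family
#' @param scale amplitude scale of the exponential-sine family
#' @export
prc_exp_sine <- function(a, C, scale = 1) {
  for (nm in c("a", "C", "scale")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
      stop("parameter '", nm, "' must be a finite number")
  }
  new_prc("exp_sine", params = list(a = a, C = C, scale = scale))
}

#' @rdname prc_double_sine
#' @param phase,value strictly increasing phases in `[0, 2*pi)` (>= 16 of
#'   them) and the PRC values sampled there
#' @export
prc_tabulated <- function(phase, value) {
  if (length(phase) != length(value)) stop("phase and value lengths differ")
  if (length(phase) < 16) stop("tabulated PRCs need at least 16 samples")
  if (any(diff(phase) <= 0)) stop("phases must be strictly increasing")
  if (min(phase) < 0 || max(phase) >= 2 * pi)
    stop("phases must lie in [0, 2*pi)")
  if (!all(is.finite(value))) stop("non-finite PRC values")
  # periodic cubic interpolation; close the period by wrapping the first point
  fun <- stats::splinefun(c(phase, phase[1] + 2 * pi), c(value, value[1]),
                          method = "periodic")
  new_prc("tabulated", params = list(),
          table = tibble::tibble(phase_rad = phase, prc_value = value),
          fun = fun)
}

new_prc <- function(kind, params, table = NULL, fun = NULL) {
  structure(list(kind = kind, params = params, table = table, fun = fun),
            class = "prc_spec")
}

#' @export
print.prc_spec <- function(x, ...) {
  cat("<prc_spec>", x$kind)
  if (length(x$params))
    cat(" (", paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", "), ")", sep = "")
  if (!is.null(x$table)) cat(" [", nrow(x$table), "samples ]")
  cat("\n")
  invisible(x)
}

#' Evaluate a PRC
#'
#' Evaluation is 2*pi-periodic; the argument is wrapped into `[0, 2*pi)`.
#'
#' @param prc a `prc_spec`
#' @param theta numeric vector of phases (radians)
#' @return numeric vector `Delta(theta)`
#' @export
prc_eval <- function(prc, theta) {
  stopifnot(inherits(prc, "prc_spec"))
  x <- theta %% (2 * pi)
  switch(prc$kind,
    double_sine = {
      a <- prc$params$a; b <- prc$params$b
      sin(a) - sin(x + a) + b * sin(2 * x)
    },
    exp_sine = {
      a <- prc$params$a; C <- prc$params$C; s <- prc$params$scale
      s * (sin(a) - sin(x + a)) * exp(C * (x - 2 * pi))
    },
    tabulated = prc$fun(x),
    stop("unknown PRC kind ", prc$kind)
  )
}

#' DC (mean) component of a PRC
#'
#' The constant Fourier coefficient `a0 = (1/2/pi) integral of Delta`. Low
#' `|a0|` characterizes "good synchronizers": the susceptibility to common
#' input is maximal when the DC component vanishes.
#'
#' @param prc a `prc_spec`
#' @param n quadrature grid size for parametric kinds
#' @return scalar `a0`
#' @export
dc_component <- function(prc, n = 512) {
  stopifnot(inherits(prc, "prc_spec"))
  if (prc$kind == "tabulated") {
    # trapezoidal mean over the table, closed periodically
    ph <- c(prc$table$phase_rad, prc$table$phase_rad[1] + 2 * pi)
    v <- c(prc$table$prc_value, prc$table$prc_value[1])
    sum(diff(ph) * (v[-1] + v[-length(v)]) / 2) / (2 * pi)
  } else {
    mean(prc_eval(prc, 2 * pi * (seq_len(n) - 1) / n))
  }
}

#' PRC cross-correlation h_nm
#'
#' Computes `h_nm(phi) = (1/2/pi) integral Delta_n(theta) *
#' Delta_m(theta + phi) dtheta`, the phase function through which a PRC pair
#' enters the stationary phase-difference theory. `h_nn` is even with
#' `h_nn(0) = mean(Delta_n^2) > 0` for any nonzero PRC, and
#' `h_nm(phi) = h_mn(-phi)`.
#'
#' @param prc_n,prc_m `prc_spec` objects
#' @param n grid size (power of two, default 256)
#' @return a [periodic_fn()]
#' @export
cross_correlation_h <- function(prc_n, prc_m, n = 256) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  dn <- prc_eval(prc_n, th)
  dm <- prc_eval(prc_m, th)
  # circular correlation via FFT: sum_j dn_j dm_{j+l}
  cc <- Re(stats::fft(Conj(stats::fft(dn)) * stats::fft(dm),
                      inverse = TRUE)) / n
  periodic_fn(cc / n)
}

#' Least-squares fit of the exponential-sine PRC family
#'
#' Fits `scale * (sin(a) - sin(x + a)) * exp(C*(x - 2*pi))` to a tabulated
#' PRC by Levenberg-Marquardt least squares. Initialization uses the phase
#' of the first Fourier harmonic for `a` and the log-ratio of early/late
#' table magnitudes for `C`, which avoids the family's local minima. The
#' sign ambiguity `(scale, a) -> (-scale, a + pi)` is resolved by reporting
#' `scale > 0` and `a` in `(-pi, pi]`.
#'
#' @param table a tabulated `prc_spec`, or a data frame with columns
#'   `phase_rad`, `prc_value`
#' @return list with `a`, `C`, `scale`, `fit_residual` (mean squared
#'   deviation on the table grid) and `prc` (the fitted `prc_spec`)
#' @export
fit_exp_sine <- function(table) {
  if (inherits(table, "prc_spec")) {
    if (table$kind != "tabulated") stop("expected a tabulated PRC")
    table <- table$table
  }
  x <- table$phase_rad
  v <- table$prc_value
  if (all(v == 0)) stop("degenerate tabulated PRC: all values are zero")

  # first-harmonic phase -> a ; the base shape -sin(x + a) has cosine
  # coefficient -sin(a) and sine coefficient -cos(a)
  ccos <- 2 * mean(v * cos(x))
  csin <- 2 * mean(v * sin(x))
  a0 <- atan2(-ccos, -csin)
  q <- length(x) %/% 4
  early <- mean(abs(v[seq_len(q)]))
  late <- mean(abs(v[(length(x) - q + 1):length(x)]))
  C0 <- if (early > 0 && late > 0)
    log(early / late) / (mean(x[seq_len(q)]) - mean(x[(length(x) - q + 1):length(x)]))
  else 0
  if (!is.finite(C0)) C0 <- 0
  C0 <- max(-2, min(2, C0))
  s0 <- max(stats::sd(v) / stats::sd((sin(a0) - sin(x + a0)) * exp(C0 * (x - 2 * pi))), 1e-6)

  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ s * (sin(a) - sin(x + a)) * exp(C * (x - 2 * pi)),
      start = list(a = a0, C = C0, s = s0),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("exponential-sine fit did not converge (start a=", signif(a0, 3),
           ", C=", signif(C0, 3), ", scale=", signif(s0, 3), "): ",
           conditionMessage(e))
  )
  p <- as.list(stats::coef(fit))
  if (p$s < 0) { p$s <- -p$s; p$a <- p$a + pi }
  p$a <- ((p$a + pi) %% (2 * pi)) - pi
  resid <- mean(stats::resid(fit)^2)
  structure(list(a = p$a, C = p$C, scale = p$s, fit_residual = resid,
                 prc = prc_exp_sine(p$a, p$C, p$s)),
            class = "exp_sine_fit")
}

#' Synthetic tabulated PRC
#'
#' Samples a parametric PRC on a uniform grid and adds Gaussian noise,
#' emulating a PRC estimated from noisy spike-time measurements. This is
#' the fixture generator that exercises the tabulated/fitting path.
#'
#' @param prc the underlying `prc_spec`
#' @param n number of samples (default 64)
#' @param noise_sd standard deviation of the additive noise, in the PRC's
#'   units (e.g. 5 percent of the peak)
#' @param seed optional integer seed
#' @return a tabulated `prc_spec`
#' @export
synthetic_prc_table <- function(prc, n = 64, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ph <- 2 * pi * (seq_len(n) - 1) / n
  v <- prc_eval(prc, ph) + stats::rnorm(n, 0, noise_sd)
  prc_tabulated(ph, v)
}

#' Read / write tabulated PRCs as CSV
#'
#' Two-column CSV with header `phase_rad,prc_value`, phases in `[0, 2*pi)`.
#'
#' @param path file path
#' @return `read_prc_csv` returns a tabulated `prc_spec`.
#' @export
read_prc_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("phase_rad", "prc_value") %in% names(d)))
    stop("expected columns phase_rad, prc_value in ", path)
  prc_tabulated(d$phase_rad, d$prc_value)
}

#' @rdname read_prc_csv
#' @param prc a `prc_spec` to export
#' @param n grid size used to sample parametric PRCs
#' @export
write_prc_csv <- function(prc, path, n = 256) {
  if (prc$kind == "tabulated") {
    d <- prc$table
  } else {
    ph <- 2 * pi * (seq_len(n) - 1) / n
    d <- data.frame(phase_rad = ph, prc_value = prc_eval(prc, ph))
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
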