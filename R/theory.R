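#' OU-filtered PRC cross-correlation g_nm
#'
#' Convolves the PRC cross-correlation `h_nm(phi)` with the stationary
#' autocorrelation kernel of the OU noise,
#' `g_nm(phi) = integral h_nm(phi + s) * exp(-|s|/tau)/(2*tau) ds`.
#' In Fourier terms harmonic `k` of `h` is multiplied by
#' `1/(1 + k^2 tau^2)`; since the kernel has unit mass, `tau -> 0`
#' (white noise) returns `h_nm` unchanged and constants pass through
#' unaltered.
#'
#' @param prc_n,prc_m `prc_spec` objects
#' @param tau OU time constant (> 0)
#' @param n grid size
#' @return a [periodic_fn()] holding `g_nm`
#' @export
filtered_correlation <- function(prc_n, prc_m, tau, n = 256) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  h <- cross_correlation_h(prc_n, prc_m, n)
  pf_apply_gain(h, function(k) 1 / (1 + k^2 * tau^2))
}

#' Assemble the stationary phase-difference problem
#'
#' Builds the coefficients of the first-order periodic boundary value
#' problem satisfied by the stationary density `R(phi)` of the phase
#' difference `phi = theta2 - theta1` between two oscillators driven by
#' partially correlated OU noise:
#'
#' \deqn{\frac{d}{d\phi}\{[c\,g(\phi) - C_1]R(\phi)\} +
#'       (2\omega/\tau - C_2)R(\phi) = K, \quad K = \frac{2\omega/\tau - C_2}{2\pi}}
#'
#' with `R` and `g` 2*pi-periodic and `R` integrating to 1 over a period.
#' The transport coefficient combines the filtered autocorrelations of the
#' unshared noise, `C1 = g11(0) + g22(0)`, with the filtered
#' cross-correlation of the shared noise, `g(phi) = 2*g12(phi)`. The
#' constant `C2` is the noise-induced frequency-shift asymmetry
#' `2*(nu1 - nu2)` with `nu_j = integral_0^inf h_jj'(s) rho_tau(s) ds`; it
#' vanishes when the PRCs are identical (then `g` is also even). `K` is
#' forced by integrating the equation over one period and is carried as a
#' consistency value, never a free input.
#'
#' All quantities use the normalization in which `h_nm` carries a `1/2/pi`
#' prefactor and in which the correlated drive has tau-independent power
#' (the variance-normalized OU process; see the Langevin simulator). The
#' `1/tau` weighting of the frequency difference is what produces the
#' resonance of synchrony with the noise time constant for detuned pairs:
#' the detuning-to-transport ratio scales as `(1 + tau^2)/tau`, minimal at
#' `tau = 1`.
#'
#' @param prc1,prc2 `prc_spec` objects
#' @param tau OU time constant (> 0)
#' @param c input correlation in `[0, 1]`
#' @param omega frequency-difference coefficient
#' @param n grid size for `g`
#' @return an object of class `stationary_problem` with fields `g`
#'   (a [periodic_fn()]), `C1`, `C2`, `K`, `c`, `tau`, `omega`, the PRC
#'   pair, and a `degenerate` flag set when the transport coefficient
#'   `C1 - c*max(g)` loses positivity (perfect-synchrony limit).
#' @examples
#' pr <- prc_double_sine(0.1, 0.32)
#' prob <- build_problem(pr, prc_double_sine(0.6, 0.3), tau = 1, c = 0.8)
#' prob$C1
#' @export
build_problem <- function(prc1, prc2, tau, c, omega = 0, n = 256) {
  stopifnot(inherits(prc1, "prc_spec"), inherits(prc2, "prc_spec"))
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(c) || c < 0 || c > 1) stop("c must lie in [0, 1]")
  h11 <- cross_correlation_h(prc1, prc1, n)
  h22 <- cross_correlation_h(prc2, prc2, n)
  gain <- function(k) 1 / (1 + k^2 * tau^2)
  g11 <- pf_apply_gain(h11, gain)
  g22 <- pf_apply_gain(h22, gain)
  g12 <- pf_apply_gain(cross_correlation_h(prc1, prc2, n), gain)
  C1 <- g11$values[1] + g22$values[1]
  # C2 = 2*(nu1 - nu2); for h_jj = sum_k a_k cos(k s),
  # nu_j = -sum_k a_k k^2 tau / (2 (1 + k^2 tau^2))
  co1 <- pf_coefs(h11); co2 <- pf_coefs(h22)
  kk <- seq_along(co1$a)
  C2 <- sum(tau * kk^2 * (co2$a - co1$a) / (1 + kk^2 * tau^2))
  g <- periodic_fn(2 * g12$values)
  K <- (2 * omega / tau - C2) / (2 * pi)
  degenerate <- (C1 - c * max(g$values)) <= .Machine$double.eps^0.5 * C1
  structure(
    list(g = g, C1 = C1, C2 = C2, K = K, omega = omega, c = c, tau = tau,
         prc1 = prc1, prc2 = prc2, degenerate = degenerate),
    class = "stationary_problem")
}

#' @export
print.stationary_problem <- function(x, ...) {
  cat("<stationary_problem> tau=", x$tau, " c=", x$c, " omega=", x$omega,
      "\n  C1=", signif(x$C1, 6), " C2=", signif(x$C2, 6),
      " K=", signif(x$K, 6),
      if (x$degenerate) "  [degenerate transport]" else "", "\n", sep = "")
  invisible(x)
}

#' Solve the stationary-density boundary value problem
#'
#' Spectral solution of the periodic first-order BVP assembled by
#' [build_problem()]. The density is expanded in Fourier harmonics
#' `R(phi) = sum r_k exp(i k phi)`, `|k| <= n_modes`, turning the
#' equation into a dense linear system in harmonic space (multiplication
#' by the transport coefficient is a convolution, the derivative is
#' `i*k`). The `k = 0` equation is the identity `A r_0 = K` (the
#' compatibility condition that fixes `K`) and is replaced by the
#' normalization constraint `r_0 = 1/(2*pi)`. The solved density is
#' checked for residual (max-norm of the ODE on the grid) and positivity;
#' values more negative than `-1e-6` raise an error rather than being
#' clipped.
#'
#' @param problem a `stationary_problem`
#' @param n_modes number of Fourier harmonics retained on each side
#' @return a [phase_density()] on `[-pi, pi)` with provenance `"bvp"`
#' @export
solve_density <- function(problem, n_modes = 128) {
  stopifnot(inherits(problem, "stationary_problem"))
  if (problem$degenerate)
    stop("degenerate transport coefficient (C1 - c*max(g) <= 0): ",
         "the stationary density is a delta limit; use closed_form_op() ",
         "for the homogeneous c -> 1 limit")
  ng <- problem$g$n
  m <- min(as.integer(n_modes), ng %/% 2 - 1L)
  A <- 2 * problem$omega / problem$tau - problem$C2
  K <- A / (2 * pi)
  # Fourier coefficients of u = c*g - C1, indexed by signed harmonic
  kg <- pf_harmonics(ng)
  uco <- problem$c * problem$g$coef
  uco[kg == 0] <- uco[kg == 0] - problem$C1
  ucof <- function(l) { # coefficient of e^{i l phi}, 0 outside range
    out <- complex(length(l))
    ok <- abs(l) <= ng %/% 2 - 1L
    idx <- ifelse(l >= 0, l + 1L, ng + l + 1L)
    out[ok] <- uco[idx[ok]]
    out
  }
  ks <- (-m):m
  nk <- length(ks)
  M <- matrix(0 + 0i, nk, nk)
  for (r in seq_len(nk)) {
    k <- ks[r]
    M[r, ] <- 1i * k * ucof(k - ks)
    M[r, r] <- M[r, r] + A
  }
  b <- complex(nk)
  i0 <- which(ks == 0)
  M[i0, ] <- 0; M[i0, i0] <- 1
  b[i0] <- 1 / (2 * pi)
  rk <- tryCatch(solve(M, b), error = function(e)
    stop("harmonic system is singular or ill-conditioned; ",
         "try more modes (n_modes > ", n_modes, ")"))
  # synthesize on the g grid
  co <- complex(ng)
  co[ifelse(ks >= 0, ks + 1L, ng + ks + 1L)] <- rk
  R <- Re(stats::fft(co, inverse = TRUE))
  grid <- problem$g$grid
  u <- Re(stats::fft(uco, inverse = TRUE))
  res <- max(abs(pf_deriv_values(u * R) + A * R - K))
  if (res > 1e-7 * max(1, max(abs(R))))
    stop("BVP residual ", signif(res, 3),
         " exceeds tolerance; try more modes (n_modes > ", n_modes, ")")
  if (min(R) < -1e-6)
    stop("solved density is negative (min ", signif(min(R), 3),
         "): insufficient resolution or invalid problem")
  R[R < 0] <- 0
  R <- R / (sum(R) * 2 * pi / ng)
  phi <- wrap_pi(grid)
  ord <- order(phi)
  phase_density(phi[ord], R[ord], provenance = "bvp")
}

#' Closed-form stationary density for a homogeneous pair
#'
#' For identical PRCs and no frequency difference the BVP integrates
#' immediately to `R(phi) = N / (C1 - c*g(phi))`, a symmetric density
#' peaked at `phi = 0`. Written in terms of the single filtered
#' autocorrelation `g_hom` of the shared PRC this is
#' `R(phi) = N / (1 - c * g_hom(phi)/g_hom(0))`.
#'
#' @param prc the common `prc_spec`
#' @param tau OU time constant
#' @param c input correlation; must be < 1 (at `c = 1` the density is a
#'   delta function and an error is raised)
#' @param n output grid size
#' @return a [phase_density()] with provenance `"closed_form"`
#' @export
closed_form_density <- function(prc, tau, c, n = 256) {
  if (c >= 1) stop("c = 1 is the perfect-synchrony delta limit; ",
                   "closed_form_op() reports its order parameter")
  g <- filtered_correlation(prc, prc, tau, n)
  gamma <- g$values / g$values[1]
  grid <- 2 * pi * (seq_len(n) - 1) / n
  R <- 1 / (1 - c * gamma)
  R <- R / (sum(R) * 2 * pi / n)
  phi <- wrap_pi(grid)
  ord <- order(phi)
  phase_density(phi[ord], R[ord], provenance = "closed_form")
}

#' Order parameter of the homogeneous closed-form density
#'
#' Computes `OP = integral cos(phi) R(phi) dphi` for the closed-form
#' homogeneous density by adaptive quadrature on the analytic expression,
#' which stays accurate arbitrarily close to the `c -> 1` delta limit
#' (where a fixed grid would under-resolve the peak).
#'
#' @inheritParams closed_form_density
#' @return scalar order parameter in `[0, 1]`
#' @export
closed_form_op <- function(prc, tau, c) {
  if (c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (c == 1) return(1)
  g <- filtered_correlation(prc, prc, tau)
  co <- pf_coefs(g)
  keep <- which(abs(co$a) > 1e-14 * max(abs(co$a)))
  gam <- function(phi) {
    v <- co$a0 + vapply(phi, function(p) sum(co$a[keep] * cos(keep * p)),
                        numeric(1))
    v / (co$a0 + sum(co$a[keep]))
  }
  den <- function(phi) 1 / (1 - c * gam(phi))
  Z <- stats::integrate(den, -pi, pi, rel.tol = 1e-10,
                        subdivisions = 2000L)$value
  Cc <- stats::integrate(function(p) cos(p) * den(p), -pi, pi,
                         rel.tol = 1e-10, subdivisions = 2000L)$value
  Cc / Z
}

#' Small-correlation expansion of the stationary density
#'
#' Expands `R(phi) = R0 + c*R1(phi) + O(c^2)`. The zeroth order is the
#' uniform density `R0 = 1/(2*pi)`; the first-order balance gives, in
#' Fourier space, `R1_k = -i k g_k R0 / (A - i k C1)` with
#' `A = 2*omega/tau - C2`. The linear-in-c slope of the order parameter is
#' `2*pi*|R1_(-1)|`, which for single-harmonic PRCs reproduces the analytic
#' susceptibility ordering of homogeneous vs heterogeneous pairs.
#'
#' @param problem a `stationary_problem` (its `c` field is not used; the
#'   expansion is in the correlation)
#' @return list with `R0`, `R1` (a [periodic_fn()]), and
#'   `op_linear_coefficient`
#' @export
small_c_expansion <- function(problem) {
  stopifnot(inherits(problem, "stationary_problem"))
  g <- problem$g
  n <- g$n
  k <- pf_harmonics(n)
  A <- 2 * problem$omega / problem$tau - problem$C2
  R0 <- 1 / (2 * pi)
  R1c <- -1i * k * g$coef * R0 / (A - 1i * k * problem$C1)
  R1c[k == 0] <- 0
  R1c[k == n / 2] <- 0
  R1 <- periodic_fn(Re(stats::fft(R1c, inverse = TRUE)))
  slope <- 2 * pi * Mod(R1c[which(k == -1)])
  list(R0 = R0, R1 = R1, op_linear_coefficient = slope)
}

#' Interpolate a phase density at arbitrary phases
#'
#' Periodic linear interpolation of a [phase_density()]; used to compare
#' densities computed on different grids (e.g. BVP vs Monte Carlo bins).
#'
#' @param density a [phase_density()]
#' @param phi phases (radians, any real values)
#' @return density values at `phi`
#' @export
density_interp <- function(density, phi) {
  x <- c(density$phi, density$phi[1] + 2 * pi)
  y <- c(density$density, density$density[1])
  p <- density$phi[1] + (phi - density$phi[1]) %% (2 * pi)
  stats::approx(x, y, xout = p, rule = 2)$y
}

#' Export densities and problems as CSV
#'
#' `write_density_csv` writes `phi_rad,density`; `write_problem_csv`
#' writes the `g` grid (`phi_rad,g`) and a scalar sidecar
#' (`C1,C2,K,tau,c,omega`).
#'
#' @param density a [phase_density()]
#' @param path,g_path,scalars_path output file paths
#' @export
write_density_csv <- function(density, path) {
  utils::write.csv(data.frame(phi_rad = density$phi,
                              density = density$density),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_density_csv
#' @param problem a `stationary_problem`
#' @export
write_problem_csv <- function(problem, g_path, scalars_path) {
  utils::write.csv(data.frame(phi_rad = problem$g$grid, g = problem$g$values),
                   g_path, row.names = FALSE)
  utils::write.csv(data.frame(C1 = problem$C1, C2 = problem$C2,
                              K = problem$K, tau = problem$tau,
                              c = problem$c, omega = problem$omega),
                   scalars_path, row.names = FALSE)
  invisible(g_path)
}
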