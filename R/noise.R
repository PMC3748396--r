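#' Correlated Ornstein-Uhlenbeck noise pair
#'
#' Simulates two OU processes `x' = -x/tau + xi_x/tau`,
#' `y' = -y/tau + xi_y/tau` whose driving white noises have unit intensity
#' and cross-intensity `c` (the input correlation). The correlation is
#' induced by a shared/private increment decomposition
#' `xi = sqrt(c)*xi_common + sqrt(1-c)*xi_private`, the minimal symmetric
#' construction with the required cross-intensity; with `c = 1` the two
#' paths are bitwise identical. Integration is Euler-Maruyama, matching the
#' Langevin simulator; initial conditions are drawn from the stationary
#' Gaussian (variance `1/(2*tau)`, covariance `c/(2*tau)`) so the paths are
#' stationary from the first sample.
#'
#' @param tau noise time constant (> 0); the stationary autocorrelation is
#'   `exp(-|s|/tau) / (2*tau)`
#' @param c input correlation in `[0, 1]`
#' @param dt time step (a warning is issued above `tau/5`)
#' @param T total simulated time
#' @param seed optional integer seed
#' @param method `"euler"` (Euler-Maruyama, matching the Langevin
#'   simulator) or `"exact"` (the exact exponential update of the OU
#'   transition density, available as a discretization cross-check)
#' @return a tibble with columns `t`, `x`, `y`; attributes `tau`, `c`,
#'   `dt`, `seed`
#' @examples
#' tr <- simulate_ou_pair(tau = 1, c = 0.8, dt = 0.05, T = 50, seed = 1)
#' stats::cor(tr$x, tr$y)
#' @export
simulate_ou_pair <- function(tau, c, dt, T, seed = NULL,
                             method = c("euler", "exact")) {
  method <- match.arg(method)
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  if (!is.finite(c) || c < 0 || c > 1) stop("c must lie in [0, 1]")
  if (!is.finite(dt) || dt <= 0) stop("dt must be positive")
  if (method == "euler" && dt > tau / 5)
    warning("dt > tau/5: Euler-Maruyama discretization of the OU pair is coarse")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(T / dt)
  zc <- stats::rnorm(n)
  zx <- stats::rnorm(n)
  zy <- stats::rnorm(n)
  sq <- if (method == "euler") sqrt(dt) / tau
        else sqrt((1 - exp(-2 * dt / tau)) / (2 * tau))
  ex <- sq * (sqrt(c) * zc + sqrt(1 - c) * zx)
  ey <- sq * (sqrt(c) * zc + sqrt(1 - c) * zy)
  # stationary start, with the right cross-covariance
  s0 <- stats::rnorm(3)
  x0 <- sqrt(1 / (2 * tau)) * (sqrt(c) * s0[1] + sqrt(1 - c) * s0[2])
  y0 <- sqrt(1 / (2 * tau)) * (sqrt(c) * s0[1] + sqrt(1 - c) * s0[3])
  a <- if (method == "euler") 1 - dt / tau else exp(-dt / tau)
  x <- stats::filter(ex, a, method = "recursive", init = x0)
  y <- stats::filter(ey, a, method = "recursive", init = y0)
  x <- c(x0, as.numeric(x))
  y <- c(y0, as.numeric(y))
  out <- tibble::tibble(t = seq(0, by = dt, length.out = n + 1), x = x, y = y)
  attr(out, "tau") <- tau; attr(out, "c") <- c
  attr(out, "dt") <- dt; attr(out, "seed") <- seed
  class(out) <- c("ou_pair_trace", class(out))
  out
}

#' Stationary moments of the OU process
#'
#' Closed-form stationary statistics of `x' = -x/tau + xi/tau` with
#' unit-intensity white noise: variance `1/(2*tau)` and autocorrelation
#' `exp(-|s|/tau) / (2*tau)`. The autocorrelation kernel integrates to 1
#' for every `tau`, which is why the `tau -> 0` limit of the filtered
#' theory recovers the white-noise results.
#'
#' @param tau noise time constant (> 0)
#' @return list with `variance` and `acf`, a function of the lag
#' @export
ou_stationary_moments <- function(tau) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be positive")
  list(variance = 1 / (2 * tau),
       acf = function(s) exp(-abs(s) / tau) / (2 * tau))
}
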