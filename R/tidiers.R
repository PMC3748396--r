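#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a stationary problem
#'
#' @param x a `stationary_problem`
#' @param ... unused
#' @return one-row tibble of the problem constants
#' @method tidy stationary_problem
#' @export
tidy.stationary_problem <- function(x, ...) {
  tibble::tibble(C1 = x$C1, C2 = x$C2, K = x$K,
                 tau = x$tau, c = x$c, omega = x$omega,
                 degenerate = x$degenerate)
}

#' Tidy / glance an exponential-sine PRC fit
#'
#' @param x an `exp_sine_fit` from [fit_exp_sine()]
#' @param ... unused
#' @return `tidy`: one row per parameter; `glance`: one-row fit summary
#' @method tidy exp_sine_fit
#' @export
tidy.exp_sine_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "C", "scale"),
                 estimate = c(x$a, x$C, x$scale))
}

#' @rdname tidy.exp_sine_fit
#' @method glance exp_sine_fit
#' @export
glance.exp_sine_fit <- function(x, ...) {
  tibble::tibble(fit_residual = x$fit_residual)
}
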