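#' Plot a phase-difference density
#'
#' @param object a [phase_density()]
#' @param ... unused
#' @return a ggplot
#' @method autoplot phase_density
#' @export
autoplot.phase_density <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$phi, y = .data$density)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1 / (2 * pi), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(phi), y = expression(R(phi)),
                  subtitle = paste("provenance:", attr(object, "provenance"))) +
    ggplot2::theme_minimal()
}

#' Plot a sweep result
#'
#' Order parameter (and peak angle, as a second facet) against the sweep
#' variable.
#'
#' @param object a `sweep_result`
#' @param ... unused
#' @return a ggplot
#' @method autoplot sweep_result
#' @export
autoplot.sweep_result <- function(object, ...) {
  var <- attr(object, "sweep_variable")
  long <- tidyr::pivot_longer(
    dplyr::select(object, dplyr::all_of(c(var, "OP", "peak_angle"))),
    c("OP", "peak_angle"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[var]], y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = var) +
    ggplot2::theme_minimal()
}

#' Plot a PRC
#'
#' @param prc a `prc_spec`
#' @param n evaluation grid size
#' @return a ggplot
#' @export
plot_prc <- function(prc, n = 256) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  d <- tibble::tibble(theta = th, delta = prc_eval(prc, th))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$theta, y = .data$delta)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = expression(theta), y = expression(Delta(theta))) +
    ggplot2::theme_minimal()
}
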