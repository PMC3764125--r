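need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Plot a VNPC comparison
#'
#' Observed versus simulated percentile curves per descriptor.
#'
#' @param x A `cel_vnpc` (from [vnpc()]).
#' @return A ggplot object.
#' @export
plot_vnpc <- function(x) {
  need_ggplot()
  ggplot2::ggplot(x, ggplot2::aes(x = .data$percentile)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed,
                                    linetype = "observed")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated,
                                    linetype = "simulated")) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = "percentile", y = "descriptor value",
                  linetype = NULL) +
    ggplot2::theme_bw()
}

#' Plot prediction intervals of the VNPC descriptors
#'
#' @param x A `cel_pi` (from [prediction_intervals()]).
#' @return A ggplot object.
#' @export
plot_prediction_intervals <- function(x) {
  need_ggplot()
  ggplot2::ggplot(x, ggplot2::aes(x = .data$percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "red", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "red",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$observed)) +
    ggplot2::facet_wrap(~descriptor, scales = "free_y") +
    ggplot2::labs(x = "percentile", y = "descriptor value") +
    ggplot2::theme_bw()
}

#' Plot the variance-versus-mean predicted interval
#'
#' Natural-log scale, with the identity line; observed per-subject pairs
#' overlaid.
#'
#' @param x A `cel_varmean` (from [variance_mean_pi()]).
#' @return A ggplot object.
#' @export
plot_variance_mean <- function(x) {
  need_ggplot()
  b <- x$bins
  ggplot2::ggplot(b, ggplot2::aes(x = log(.data$mean_median))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = log(pmax(.data$var_lower,
                                                      1e-3)),
                                      ymax = log(.data$var_upper)),
                         fill = "blue", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = log(.data$var_median)),
                       colour = "blue") +
    ggplot2::geom_abline(slope = 1, intercept = 0) +
    ggplot2::geom_point(data = x$observed,
                        ggplot2::aes(x = log(.data$mean),
                                     y = log(pmax(.data$variance, 1e-3)))) +
    ggplot2::labs(x = "log mean CELs per subject",
                  y = "log variance of CELs per subject") +
    ggplot2::theme_bw()
}

#' Plot the randomization-test null distribution
#'
#' Histogram of the OFVs under randomized dose architectures with the
#' true-architecture OFV marked.
#'
#' @param x A `cel_randtest` (from [randomization_test()]).
#' @return A ggplot object.
#' @export
plot_randomization <- function(x) {
  need_ggplot()
  d <- data.frame(ofv = x$ofv_null)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ofv)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = x$ofv_true, colour = "red",
                        linewidth = 1) +
    ggplot2::labs(x = "OFV under randomized dose architectures",
                  y = "count") +
    ggplot2::theme_bw()
}
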