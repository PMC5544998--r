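#' Plot a phase-difference histogram
#'
#' Bar chart of pair counts per difference bin (0, 2, ..., 12 h of circular
#' phase difference). The rightmost bar is the counter-phase bin.
#'
#' @param object A [difference_histogram()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.diff_histogram <- function(object, ...) {
  df <- as_tibble(object)
  df$diff_h <- df$bin * 2
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$diff_h), y = .data$count)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "absolute phase difference (h)", y = "probe pairs",
                  title = attr(object, "dataset")) +
    ggplot2::theme_minimal()
}

#' Plot a Poisson goodness-of-fit result
#'
#' Observed pair counts per bin with the fitted Poisson expectation
#' overlaid; a counter-phase excess shows as the observed bin-6 bar rising
#' far above the expected point.
#'
#' @param object A [poisson_gof()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.poisson_gof <- function(object, ...) {
  df <- tidy(object)
  df$diff_h <- df$bin * 2
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$diff_h))) +
    ggplot2::geom_col(ggplot2::aes(y = .data$observed), fill = "grey35") +
    ggplot2::geom_point(ggplot2::aes(y = .data$expected), colour = "red3",
                        size = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$expected, group = 1),
                       colour = "red3") +
    ggplot2::labs(x = "absolute phase difference (h)", y = "probe pairs",
                  subtitle = sprintf("lambda = %.3g, X2 = %.3g, p = %.2g",
                                     object$lambda, object$X2, object$p_asym)) +
    ggplot2::theme_minimal()
}

#' Plot an expression panel
#'
#' Time courses of (a subset of) probes; replicate samples are shown as
#' points, the replicate mean as a line.
#'
#' @param object An [expr_ts()] panel.
#' @param probes Probe ids to show (default: the first 6).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.expr_ts <- function(object, probes = head(rownames(object$values), 6L),
                             ...) {
  long <- as_tibble(object)
  long <- dplyr::filter(long, .data$probe_id %in% probes)
  means <- long |>
    dplyr::group_by(.data$probe_id, .data$time_h) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_line(data = means) +
    ggplot2::facet_wrap(~probe_id, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "normalized intensity") +
    ggplot2::theme_minimal()
}

#' Plot the two isoform trajectories and their sum
#'
#' Evaluates the analytic solution of the two-isoform model and draws n1,
#' n2 and n1 + n2; under rectifier parameters the sum is a flat line.
#'
#' @param params A [model_params()] object.
#' @param times Time grid in hours (default two 24 h periods at 0.25 h).
#' @return A ggplot object.
#' @examples
#' plot_isoforms(rectifier_params())
#' @export
plot_isoforms <- function(params, times = seq(0, 48, by = 0.25)) {
  traj <- evaluate_analytic(params, times)
  long <- tidyr::pivot_longer(traj, c("n1", "n2", "total"),
                              names_to = "component", values_to = "abundance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$abundance,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(n1 = "#1b9e77", n2 = "#d95f02",
                                            total = "grey20")) +
    ggplot2::labs(x = "time (h)", y = "abundance") +
    ggplot2::theme_minimal()
}
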