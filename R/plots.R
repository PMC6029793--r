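#' Plot framewise displacement and DVARS traces
#'
#' One line per run, faceted by metric, with the FD flagging threshold drawn
#' on the FD panel.
#'
#' @param object A `qc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot qc_report
#' @export
autoplot.qc_report <- function(object, ...) {
  long <- dplyr::bind_rows(
    tidyr::unnest(
      dplyr::transmute(object, .data$subject, .data$condition,
                       metric = "FD (mm)", value = .data$fd),
      "value"
    ),
    tidyr::unnest(
      dplyr::transmute(object, .data$subject, .data$condition,
                       metric = "DVARS", value = .data$dvars),
      "value"
    )
  )
  long <- dplyr::mutate(
    long,
    volume = stats::ave(.data$value, .data$subject, .data$condition,
                        .data$metric, FUN = seq_along),
    run = paste(.data$subject, .data$condition)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$volume, .data$value,
                                     group = .data$run)) +
    ggplot2::geom_line(alpha = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "Volume", y = NULL, title = "Run-level QC traces") +
    ggplot2::theme_minimal()
}

#' Plot cross-modal component correlations against their null
#'
#' Components ordered by ranking A, showing both ranking statistics and the
#' 2.5/97.5 percentiles of the scheme-A permutation null.
#'
#' @param object A `ranking_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ranking_table
#' @export
autoplot.ranking_table <- function(object, ...) {
  nulls <- attr(object, "nulls")
  band <- stats::quantile(nulls$A$values, c(0.025, 0.975))
  long <- tidyr::pivot_longer(
    object[, c("component", "rank_A", "r_A", "r_B")],
    c("r_A", "r_B"), names_to = "scheme", values_to = "r"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$rank_A, .data$r,
                                     colour = .data$scheme)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band[1], ymax = band[2], alpha = 0.15) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Component (ranking A order)",
                  y = "Cross-modal correlation",
                  title = "Cross-modal component rankings",
                  subtitle = "Shaded band: central 95% of the shift-permutation null") +
    ggplot2::theme_minimal()
}

#' Plot the preprocessed dialog regressor
#'
#' @param object A `dialog_regressor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dialog_regressor
#' @export
autoplot.dialog_regressor <- function(object, ...) {
  df <- tibble::tibble(
    time = (seq_along(object$values) - 0.5) * object$tr,
    value = object$values
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (s)", y = "Dialog regressor (z)",
                  title = "HRF-convolved, high-pass filtered dialog regressor") +
    ggplot2::theme_minimal()
}

#' Histogram of a shift-permutation null distribution
#'
#' @param object A `null_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot null_distribution
#' @export
autoplot.null_distribution <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = 60) +
    ggplot2::labs(x = "Null correlation", y = "Count",
                  title = sprintf("Shift-permutation null (%d values)",
                                  length(object$values))) +
    ggplot2::theme_minimal()
}
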