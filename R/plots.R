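#' Plot accuracy by group
#'
#' Dot-and-error-bar plot of group mean accuracy with twice the standard
#' error, from [summarize_accuracy()] output.
#'
#' @param summary Tibble from [summarize_accuracy()]; its first column is
#'   used as the x axis.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(summary) {
  xvar <- names(summary)[1]
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data[[xvar]], y = .data$mean_accuracy)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::labs(y = "accuracy", x = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the distribution of confidence judgments by treatment
#'
#' Folded bar chart of the 11 confidence categories (100% confident and
#' wrong, through 50%, to 100% confident and correct) per treatment,
#' mirroring how judgment distributions are typically reported for this
#' task.
#'
#' @param data Judgment tibble (filler trials are dropped).
#' @return A ggplot object.
#' @export
plot_confidence_distribution <- function(data) {
  assert_columns(data, c("treatment", "confidence_category", "col"))
  folded <- data |>
    dplyr::filter(.data$treatment != "filler") |>
    dplyr::mutate(folded = ifelse(.data$col == 1, .data$confidence_category,
                                  12L - .data$confidence_category)) |>
    dplyr::count(.data$treatment, .data$folded) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  ggplot2::ggplot(folded, ggplot2::aes(x = .data$folded,
                                       y = .data$proportion,
                                       fill = .data$folded > 6)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::scale_x_continuous(breaks = c(1, 6, 11),
                                labels = c("100% wrong", "50%",
                                           "100% correct")) +
    ggplot2::labs(x = "confidence judgment", y = "proportion") +
    ggplot2::theme_minimal()
}

#' Recovery scatter: true versus estimated subject parameters
#'
#' @param object An `ea_recovery` from [parameter_recovery()].
#' @param ... Unused.
#' @return A ggplot object (one facet per parameter, identity line).
#' @method autoplot ea_recovery
#' @export
autoplot.ea_recovery <- function(object, ...) {
  ggplot2::ggplot(object$subject_pairs,
                  ggplot2::aes(x = .data$true, y = .data$estimated)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey60") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::facet_wrap(~parameter, scales = "free") +
    ggplot2::labs(x = "true subject parameter",
                  y = "posterior-mean estimate") +
    ggplot2::theme_minimal()
}

#' Forest plot of d-prime contrasts
#'
#' @param object An `sdt_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sdt_fit
#' @export
autoplot.sdt_fit <- function(object, ...) {
  ct <- dprime_contrasts(object)
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$contrast,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        color = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = "d-prime change", y = NULL) +
    ggplot2::theme_minimal()
}
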