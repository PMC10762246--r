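#' Brier-based scoring of a confidence judgment
#'
#' Points for a single judgment: `100 * (1 - (correct - conf)^2) - 75`,
#' a proper scoring rule under which expected points are maximized by
#' reporting the true probability of being correct. A 50% judgment earns 0
#' points regardless of the outcome.
#'
#' @param correct 0/1 correctness of the choice (may be `NA` for 50%
#'   judgments, which score 0).
#' @param conf Confidence on the grid 0.50, 0.60, ..., 1.00.
#' @return Points (vectorized).
#' @examples
#' score_judgment(1, 1.0)  # 25
#' score_judgment(0, 1.0)  # -75
#' @export
score_judgment <- function(correct, conf) {
  grid_ok <- abs(conf * 10 - round(conf * 10)) < 1e-9 & conf >= 0.5 & conf <= 1
  if (any(!grid_ok)) {
    stop("`conf` must lie on the grid 0.50, 0.60, ..., 1.00")
  }
  correct <- ifelse(is.na(correct) & abs(conf - 0.5) < 1e-9, 1, correct)
  if (any(is.na(correct))) stop("`correct` may be NA only when conf = 0.5")
  100 * (1 - (correct - conf)^2) - 75
}

#' Bonus payment from total points
#'
#' $0.20 per 100 points, with a guaranteed $1 bonus below 500 points.
#'
#' @param total_points Total points earned across trials.
#' @return Bonus in dollars (vectorized).
#' @export
compute_bonus <- function(total_points) {
  pmax(1, 0.2 * total_points / 100)
}

#' Subject-level exclusion criteria
#'
#' @param max_share_full_confidence Exclude when the share of trials with
#'   100% confidence exceeds this (default 0.90).
#' @param min_accuracy Exclude when average accuracy (50% judgments
#'   excluded) falls below this (default 0.50).
#' @param max_late_responses Exclude when the number of late responses
#'   exceeds this (default 10); counted over all trials including fillers.
#' @param require_conf_correct_gt_wrong Exclude when average confidence on
#'   wrong trials strictly exceeds average confidence on correct trials.
#' @param glitch_flag_field Name of an optional logical column marking
#'   self-reported display glitches; any `TRUE` excludes the subject.
#' @return An `exclusion_criteria` object.
#' @export
exclusion_criteria <- function(max_share_full_confidence = 0.90,
                               min_accuracy = 0.50,
                               max_late_responses = 10,
                               require_conf_correct_gt_wrong = TRUE,
                               glitch_flag_field = "glitch_flag") {
  stopifnot(max_share_full_confidence > 0, max_share_full_confidence <= 1,
            min_accuracy >= 0, min_accuracy <= 1, max_late_responses >= 0)
  structure(as.list(environment()), class = "exclusion_criteria")
}

#' Apply subject-level exclusions
#'
#' Removes subjects that trigger at least one exclusion criterion and
#' reports every triggered criterion per subject (a subject may trigger
#' several). 50% judgments contribute to the full-confidence share and late
#' counts but not to accuracy or confidence calibration.
#'
#' @param data Judgment tibble.
#' @param criteria An [exclusion_criteria()].
#' @return A list of class `exclusion_result` with `data` (kept subjects)
#'   and `report` (per subject: `excluded`, logical columns per criterion,
#'   and a comma-separated `reasons` string).
#' @export
apply_subject_exclusions <- function(data, criteria = exclusion_criteria()) {
  stopifnot(inherits(criteria, "exclusion_criteria"))
  assert_columns(data, c("subject_id", "confidence_category", "confidence",
                         "correct", "late_flag"))
  glitch_col <- criteria$glitch_flag_field
  report <- data |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      full_confidence_share =
        mean(.data$confidence_category %in% c(1L, 11L)) >
          criteria$max_share_full_confidence,
      low_accuracy = below_accuracy(.data$correct, .data$confidence_category,
                                    criteria$min_accuracy),
      late_responses = sum(.data$late_flag) > criteria$max_late_responses,
      confidence_calibration = criteria$require_conf_correct_gt_wrong &&
        confidence_miscalibrated(.data$confidence, .data$correct,
                                 .data$confidence_category),
      glitch = if (glitch_col %in% names(data)) {
        any(.data[[glitch_col]], na.rm = TRUE)
      } else FALSE,
      .groups = "drop"
    )
  crit_cols <- c("full_confidence_share", "low_accuracy", "late_responses",
                 "confidence_calibration", "glitch")
  report$excluded <- Reduce(`|`, report[crit_cols])
  report$reasons <- apply(report[crit_cols], 1, function(x) {
    paste(crit_cols[which(x)], collapse = ",")
  })
  kept <- dplyr::filter(
    data, !.data$subject_id %in% report$subject_id[report$excluded])
  structure(list(data = kept, report = report), class = "exclusion_result")
}

below_accuracy <- function(correct, category, min_accuracy) {
  m <- mean(correct[category != 6L], na.rm = TRUE)
  !is.na(m) && m < min_accuracy
}

confidence_miscalibrated <- function(confidence, correct, category) {
  use <- category != 6L
  conf_wrong <- confidence[use & correct == 0]
  conf_right <- confidence[use & correct == 1]
  if (length(conf_wrong) == 0 || length(conf_right) == 0) return(FALSE)
  mean(conf_wrong) > mean(conf_right)
}

#' @export
print.exclusion_result <- function(x, ...) {
  n_exc <- sum(x$report$excluded)
  cat(sprintf("exclusion result: %d of %d subjects excluded\n",
              n_exc, nrow(x$report)))
  if (n_exc > 0) {
    print(dplyr::filter(x$report, .data$excluded)[c("subject_id", "reasons")])
  }
  invisible(x)
}

#' Trial-level filters per analysis
#'
#' Applies the trial filters each analysis requires: `"accuracy"` drops
#' filler trials and 50% judgments, `"accumulation"` drops filler and late
#' trials, `"ordinal"` drops filler trials only. Filters are idempotent; a
#' provenance column `analysis_filter` records the filter applied.
#'
#' @param data Judgment tibble.
#' @param analysis One of `"accuracy"`, `"accumulation"`, `"ordinal"`.
#' @return The filtered tibble.
#' @export
apply_trial_filters <- function(data,
                                analysis = c("accuracy", "accumulation",
                                             "ordinal")) {
  analysis <- match.arg(analysis)
  assert_columns(data, c("filler", "confidence_category", "late_flag"))
  out <- switch(analysis,
    accuracy = dplyr::filter(data, !.data$filler,
                             .data$confidence_category != 6L),
    accumulation = dplyr::filter(data, !.data$filler, !.data$late_flag),
    ordinal = dplyr::filter(data, !.data$filler)
  )
  out$analysis_filter <- analysis
  out
}

#' Accuracy summaries by group
#'
#' Mean accuracy with plus/minus twice the standard error, computed with
#' subject means as the unit of analysis.
#'
#' @param data Judgment tibble with the accuracy filter applied.
#' @param ... Grouping columns (tidy evaluation), e.g. `si_validity`.
#' @return A tibble of group means: `mean_accuracy`, `se`, `lower`,
#'   `upper`, `n_subjects`. Groups without scorable trials are flagged with
#'   a warning and returned with `NA` accuracy.
#' @export
summarize_accuracy <- function(data, ...) {
  assert_columns(data, c("subject_id", "correct"))
  by_subject <- data |>
    dplyr::group_by(.data$subject_id, ...) |>
    dplyr::summarise(acc = mean(.data$correct, na.rm = TRUE),
                     n_trials = sum(!is.na(.data$correct)),
                     .groups = "drop")
  if (any(by_subject$n_trials == 0)) {
    warning("some subject-by-group cells contain no scorable trials")
    by_subject$acc[by_subject$n_trials == 0] <- NA
  }
  by_subject |>
    dplyr::group_by(...) |>
    dplyr::summarise(
      mean_accuracy = mean(.data$acc, na.rm = TRUE),
      se = stats::sd(.data$acc, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$acc))),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(se = ifelse(is.na(.data$se), 0, .data$se),
                  lower = .data$mean_accuracy - 2 * .data$se,
                  upper = .data$mean_accuracy + 2 * .data$se)
}
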