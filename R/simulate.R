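#' Population-level truth for simulating subjects
#'
#' Describes the population from which subject-level accumulator parameters
#' are drawn, together with the shared confidence criteria and the
#' response-latency law. Defaults are calibrated to the Experiment 1
#' population-level point estimates (easy personal drift 0.90 evidence
#' units/s, social drift 0.18/s, social shift 2.41) with criteria spaced
#' 1.75 evidence units apart and a latency law whose in-window mean of
#' 1.1 s places judgments on average 3.1 s after social-information onset.
#'
#' @param n_subjects Number of subjects to simulate.
#' @param mean_delta_easy,sd_delta_easy Personal drift on easy trials
#'   (evidence units per second), population mean and SD.
#' @param mean_delta_hard,sd_delta_hard Personal drift on hard trials.
#' @param mean_delta_s,sd_delta_s Social drift (per second from
#'   social-information onset).
#' @param mean_gamma,sd_gamma Instantaneous social shift (evidence units).
#' @param mean_tau,sd_tau Color bias (+ orange / - blue).
#' @param criteria_increments Five positive spacings generating the upper
#'   confidence criteria `c6..c10`; the lower five are their mirror images.
#' @param mean_latency_s Mean response latency among in-window responses
#'   (seconds); the lognormal location is solved to match it.
#' @param sdlog_latency Lognormal scale of the latency law.
#' @return A `population_spec` object.
#' @export
population_spec <- function(n_subjects = 30,
                            mean_delta_easy = 0.90, sd_delta_easy = 0.35,
                            mean_delta_hard = 0.45, sd_delta_hard = 0.30,
                            mean_delta_s = 0.18, sd_delta_s = 0.12,
                            mean_gamma = 2.41, sd_gamma = 1.00,
                            mean_tau = 0.00, sd_tau = 0.30,
                            criteria_increments = rep(1.75, 5),
                            mean_latency_s = 1.1, sdlog_latency = 0.4) {
  spreads <- c(sd_delta_easy, sd_delta_hard, sd_delta_s, sd_gamma, sd_tau)
  if (any(spreads < 0)) stop("population spreads must be >= 0")
  if (length(criteria_increments) != 5 || any(criteria_increments <= 0)) {
    stop("`criteria_increments` must be five positive values")
  }
  if (mean_latency_s <= 0 || sdlog_latency <= 0) {
    stop("latency parameters must be positive")
  }
  structure(list(
    n_subjects = n_subjects,
    mean_delta_easy = mean_delta_easy, sd_delta_easy = sd_delta_easy,
    mean_delta_hard = mean_delta_hard, sd_delta_hard = sd_delta_hard,
    mean_delta_s = mean_delta_s, sd_delta_s = sd_delta_s,
    mean_gamma = mean_gamma, sd_gamma = sd_gamma,
    mean_tau = mean_tau, sd_tau = sd_tau,
    criteria_increments = criteria_increments,
    mean_latency_s = mean_latency_s, sdlog_latency = sdlog_latency
  ), class = "population_spec")
}

#' Confidence criteria from their positive increments
#'
#' @param increments Five positive spacings for `c6..c10`.
#' @return The ten mirror-symmetric criteria `c1 < ... < c10`.
#' @export
make_criteria <- function(increments) {
  stopifnot(length(increments) == 5, all(increments > 0))
  upper <- cumsum(increments)
  c(-rev(upper), upper)
}

#' Draw subject-level accumulator parameters
#'
#' Samples one parameter set per subject from the population's normal
#' distributions; the confidence criteria are shared across subjects and
#' attached as the `"criteria"` attribute.
#'
#' @param pop A [population_spec()].
#' @param seed Integer seed.
#' @return A tibble with columns `subject_id`, `delta_easy`, `delta_hard`,
#'   `delta_s`, `gamma`, `tau`, and attribute `criteria`.
#' @export
draw_subject_parameters <- function(pop, seed = 1) {
  stopifnot(inherits(pop, "population_spec"))
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  n <- pop$n_subjects
  out <- tibble::tibble(
    subject_id = seq_len(n),
    delta_easy = rnorm(n, pop$mean_delta_easy, pop$sd_delta_easy),
    delta_hard = rnorm(n, pop$mean_delta_hard, pop$sd_delta_hard),
    delta_s = rnorm(n, pop$mean_delta_s, pop$sd_delta_s),
    gamma = rnorm(n, pop$mean_gamma, pop$sd_gamma),
    tau = rnorm(n, pop$mean_tau, pop$sd_tau)
  )
  attr(out, "criteria") <- make_criteria(pop$criteria_increments)
  out
}

# lognormal location such that E[X | X <= window] equals the target mean
latency_meanlog <- function(target_mean, sdlog, window) {
  if (target_mean >= window) stop("mean latency must lie below the window")
  f <- function(ml) {
    den <- pnorm((log(window) - ml) / sdlog)
    if (den < 1e-12) return(window - target_mean) # all mass beyond the window
    num <- exp(ml + sdlog^2 / 2) *
      pnorm((log(window) - ml - sdlog^2) / sdlog)
    num / den - target_mean
  }
  uniroot(f, c(log(target_mean) - 2, log(target_mean) + 1))$root
}

# latencies truncated to (0, window + 1]; values above `window` are late
draw_latencies <- function(n, mean_latency_s, sdlog, window_s) {
  ml <- latency_meanlog(mean_latency_s, sdlog, window_s)
  upper <- plnorm(window_s + 1, ml, sdlog)
  qlnorm(runif(n) * upper, ml, sdlog)
}

#' Simulate confidence judgments from the generative accumulation model
#'
#' For every scheduled trial, a response latency is drawn from the truncated
#' lognormal latency law, the latent evidence is drawn from
#' `Normal(E[L], DT)` on the color axis (orange positive), and the evidence
#' is binned by the shared confidence criteria into one of the 11
#' categories (`j = 1` is 100% confidence in blue, `j = 6` is 50%, `j = 11`
#' is 100% confidence in orange). Social terms are zeroed on no-social and
#' filler trials.
#'
#' @param schedule Schedule tibble covering one or more subjects (must have
#'   a `subject_id` column matching `subject_params`).
#' @param subject_params Tibble from [draw_subject_parameters()] with the
#'   shared criteria attached (or pass `criteria`).
#' @param pop A [population_spec()] supplying the latency law.
#' @param seed Integer seed.
#' @param criteria Optional override of the shared confidence criteria.
#' @return A judgment tibble: the schedule columns plus `latency_s`,
#'   `late_flag`, `dt_s`, `st_s`, `confidence_category`, `reported`,
#'   `confidence`, `correct`, `filler`.
#' @export
simulate_dataset <- function(schedule, subject_params, pop, seed = 1,
                             criteria = NULL) {
  assert_columns(schedule, c("subject_id", "treatment", "difficulty", "col",
                             "si_validity", "si_onset_ms", "deliberation_ms",
                             "response_window_ms"), "schedule")
  criteria <- criteria %||% attr(subject_params, "criteria")
  if (is.null(criteria)) stop("no confidence criteria supplied")
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  data <- dplyr::inner_join(schedule, subject_params, by = "subject_id")
  if (nrow(data) != nrow(schedule)) {
    stop("every schedule row must match a subject in `subject_params`")
  }
  window_s <- data$response_window_ms / 1000
  stopifnot(length(unique(window_s)) == 1)
  lat <- draw_latencies(nrow(data), pop$mean_latency_s, pop$sdlog_latency,
                        window_s[1])

  si <- as.numeric(!is.na(data$si_validity))
  dt <- 1 + data$deliberation_ms / 1000 + lat
  st <- ifelse(si == 1, (data$deliberation_ms - data$si_onset_ms) / 1000 + lat,
               0)
  if (any(dt <= 0)) stop("decision times must be positive")
  dp <- ifelse(data$difficulty == "easy", data$delta_easy, data$delta_hard)
  ssign <- ifelse(si == 1, data$col * data$si_validity, 0)
  mu <- data$tau + dp * dt * data$col + (data$delta_s * st + data$gamma) * ssign
  evidence <- rnorm(nrow(data), mu, sqrt(dt))
  j <- findInterval(evidence, criteria) + 1L

  out <- data |>
    dplyr::select(dplyr::all_of(names(schedule))) |>
    dplyr::mutate(
      latency_s = lat,
      late_flag = lat > window_s,
      dt_s = dt,
      st_s = st,
      confidence_category = j,
      filler = .data$treatment == "filler"
    )
  finalize_judgments(out)
}

# derive reported side, confidence, and correctness from the category
finalize_judgments <- function(data) {
  j <- data$confidence_category
  data$reported <- category_side(j)
  data$confidence <- category_confidence(j)
  data$correct <- ifelse(j == 6L, NA, as.numeric(data$reported == data$col))
  data
}

#' Simulate a complete multi-subject experiment
#'
#' Convenience wrapper: draws subject parameters, builds one randomized
#' schedule per subject, and simulates judgments.
#'
#' @param pop A [population_spec()].
#' @param config A [design_config()]; its `seed` is ignored in favor of
#'   per-subject seeds derived from `seed`.
#' @param seed Integer seed controlling all stages.
#' @return A list with `data` (judgment tibble), `subject_params`, and
#'   `criteria`.
#' @export
simulate_experiment <- function(pop, config = design_config(), seed = 1) {
  params <- draw_subject_parameters(pop, seed = seed)
  schedules <- purrr::map(seq_len(pop$n_subjects), function(s) {
    cfg <- config
    cfg$seed <- seed + 1000L + s
    build_trial_schedule(cfg, subject_id = s)
  })
  schedule <- dplyr::bind_rows(schedules)
  data <- simulate_dataset(schedule, params, pop, seed = seed + 500L)
  list(data = data, subject_params = params,
       criteria = attr(params, "criteria"))
}

pathology_levels <- function() {
  c("always-100", "below-chance", "chronic-late", "miscalibrated")
}

#' Inject pathological subjects for exclusion-rule testing
#'
#' Rewrites the judgments of selected subjects so that they violate exactly
#' one subject-level exclusion rule: `"always-100"` responders give 100%
#' confidence on more than 90% of trials, `"below-chance"` responders have
#' accuracy below 50%, `"chronic-late"` responders exceed 10 late
#' responses, and `"miscalibrated"` responders are more confident when
#' wrong than when correct. Ground-truth labels travel with the result so
#' preprocessing tests are self-verifying.
#'
#' @param data Judgment tibble from [simulate_dataset()].
#' @param spec Tibble with columns `subject_id` and `pathology` (one of
#'   `pathology_levels()`); an empty spec leaves the data unchanged.
#' @param seed Integer seed.
#' @return A list with `data` (augmented tibble) and `labels` (the spec,
#'   with the triggered exclusion reason added).
#' @export
inject_exclusion_pathologies <- function(data, spec, seed = 1) {
  if (nrow(spec) == 0) {
    return(list(data = data, labels = tibble::tibble(
      subject_id = integer(), pathology = character(), reason = character())))
  }
  assert_columns(spec, c("subject_id", "pathology"), "pathology spec")
  bad <- setdiff(spec$pathology, pathology_levels())
  if (length(bad) > 0) {
    stop("unknown pathology name(s): ", paste(bad, collapse = ", "))
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  for (k in seq_len(nrow(spec))) {
    sid <- spec$subject_id[k]
    rows <- which(data$subject_id == sid)
    if (length(rows) == 0) stop("subject ", sid, " not present in data")
    n <- length(rows)
    j <- data$confidence_category[rows]
    col <- data$col[rows]
    switch(spec$pathology[k],
      "always-100" = {
        hit <- runif(n) < 0.95
        side <- ifelse(j == 6, sample(c(-1, 1), n, replace = TRUE),
                       category_side(j))
        data$confidence_category[rows] <-
          ifelse(hit, ifelse(side >= 0, 11L, 1L), j)
      },
      "below-chance" = {
        wrong <- runif(n) < 0.7
        k_off <- sample(1:5, n, replace = TRUE)
        data$confidence_category[rows] <-
          as.integer(6 + ifelse(wrong, -col, col) * k_off)
      },
      "chronic-late" = {
        window_s <- data$response_window_ms[rows] / 1000
        late_idx <- sample(n, min(12L, n))
        data$latency_s[rows[late_idx]] <-
          window_s[late_idx] + runif(length(late_idx), 0.2, 0.8)
        data$late_flag[rows] <- data$latency_s[rows] > window_s
      },
      "miscalibrated" = {
        right <- runif(n) < 0.6
        data$confidence_category[rows] <-
          as.integer(ifelse(right, 6 + col, 6 - 5 * col))
      }
    )
    data[rows, ] <- finalize_judgments(data[rows, ])
  }
  reason_map <- c("always-100" = "full_confidence_share",
                  "below-chance" = "low_accuracy",
                  "chronic-late" = "late_responses",
                  "miscalibrated" = "confidence_calibration")
  labels <- dplyr::mutate(spec, reason = unname(reason_map[.data$pathology]))
  list(data = data, labels = labels)
}

#' Write or read a judgment dataset as CSV
#'
#' @param data Judgment tibble.
#' @param path File path.
#' @return `read_dataset()` returns the tibble; `write_dataset()` returns
#'   `path` invisibly.
#' @export
write_dataset <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
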