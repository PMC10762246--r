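#' Configuration of a within-subject trial schedule
#'
#' Describes the experimental design used in the two color-discrimination
#' experiments: six treatments (early/late by correct/wrong social
#' information, a no-social control, and short "filler" trials) arranged in
#' blocks of six trials, with jittered social-information onsets.
#'
#' @param experiment 1 or 2. Experiment 1 keeps the social cue on screen
#'   until the end of the 4 s deliberation phase; Experiment 2 shows it for
#'   500 ms in both timing conditions and allows 3 s (instead of 2 s) for
#'   the judgment.
#' @param n_blocks Number of six-trial blocks. Must be a multiple of 10 with
#'   treatment sizes divisible into the four difficulty-by-color cells
#'   (the default, 20, gives the canonical 120-trial session).
#' @param jitter_ms Half-width of the uniform jitter added to the nominal
#'   social-information onset (ms).
#' @param seed Integer seed; the schedule is a pure function of the
#'   configuration including this seed.
#'
#' @return An object of class `design_config`.
#' @export
design_config <- function(experiment = 1, n_blocks = 20, jitter_ms = 250,
                          seed = 1) {
  if (!experiment %in% c(1, 2)) stop("`experiment` must be 1 or 2")
  n_early <- 2 * n_blocks
  n_correct <- 1.4 * n_blocks # 70% of social information is correct
  if (n_blocks < 1 || n_correct != round(n_correct) ||
      n_correct %% 4 != 0 || (n_early - n_correct) %% 4 != 0 ||
      n_blocks %% 2 != 0) {
    stop("`n_blocks` = ", n_blocks, " cannot be balanced: treatment sizes ",
         "must split the 70/30 correct/wrong ratio into whole ",
         "difficulty-by-color cells (use a multiple of 10).")
  }
  structure(list(
    experiment = experiment,
    n_blocks = n_blocks,
    jitter_ms = jitter_ms,
    seed = seed,
    deliberation_ms = 4000,
    filler_deliberation_ms = 1000,
    si_onset_early_ms = 750,
    si_onset_late_ms = 3250,
    si_display_ms = if (experiment == 2) 500 else NA_real_,
    response_window_ms = if (experiment == 2) 3000 else 2000,
    stimulus_ms = 1000,
    # proportion of the dominant color, carried as metadata only
    p_dominant_easy = 0.515,
    p_dominant_hard = 0.505
  ), class = "design_config")
}

treatment_levels <- function() {
  c("early-correct", "late-correct", "early-wrong", "late-wrong",
    "no-social", "filler")
}

treatment_counts <- function(n_blocks) {
  c("early-correct" = 1.4 * n_blocks, "late-correct" = 1.4 * n_blocks,
    "early-wrong" = 0.6 * n_blocks, "late-wrong" = 0.6 * n_blocks,
    "no-social" = n_blocks, "filler" = n_blocks)
}

# balanced, shuffled difficulty-by-color cells for one treatment
balanced_cells <- function(n) {
  cells <- tidyr::expand_grid(difficulty = c("easy", "hard"), col = c(1, -1))
  cells <- cells[rep(seq_len(4), each = n / 4), ]
  cells[sample.int(n), ]
}

#' Build a balanced trial schedule
#'
#' Generates one subject's ordered trial table: `6 * n_blocks` trials in
#' blocks that each contain two early-social, two late-social, one
#' no-social, and one filler trial in randomized order. Correct and wrong
#' social information are allotted 70%/30% of the social trials within each
#' timing, and difficulty-by-color cells are exactly balanced within every
#' treatment. Social-information onsets get continuous uniform jitter.
#'
#' @param config A [design_config()].
#' @param subject_id Optional identifier stored with every trial.
#' @return A tibble with one row per trial: `subject_id`, `trial_index`,
#'   `block`, `treatment`, `difficulty`, `col` (+1 orange / -1 blue),
#'   `si_validity` (+1 correct / -1 wrong / NA), `si_onset_ms` (realized),
#'   `si_display_ms`, `deliberation_ms`, `response_window_ms`.
#' @examples
#' sched <- build_trial_schedule(design_config(seed = 42))
#' table(sched$treatment)
#' @export
build_trial_schedule <- function(config, subject_id = NA_integer_) {
  stopifnot(inherits(config, "design_config"))
  withr_seed <- config$seed
  old <- .Random.seed_exists()
  set.seed(withr_seed)
  on.exit(restore_seed(old), add = TRUE)

  nb <- config$n_blocks
  counts <- treatment_counts(nb)

  # per-treatment trial pools with balanced difficulty x color cells
  pools <- lapply(names(counts), function(tr) {
    dplyr::mutate(balanced_cells(counts[[tr]]), treatment = tr)
  })
  names(pools) <- names(counts)

  # distribute validity over the early and late slots: 2 per block,
  # 70% correct overall, shuffled across blocks
  slot_validity <- function(n_correct, n_wrong) {
    sample(rep(c("correct", "wrong"), c(n_correct, n_wrong)))
  }
  early_val <- slot_validity(counts[["early-correct"]], counts[["early-wrong"]])
  late_val <- slot_validity(counts[["late-correct"]], counts[["late-wrong"]])

  take <- function(tr) {
    row <- pools[[tr]][1, ]
    pools[[tr]] <<- pools[[tr]][-1, ]
    row
  }

  rows <- vector("list", 6 * nb)
  idx <- 0L
  for (b in seq_len(nb)) {
    block_rows <- list()
    for (k in 1:2) {
      tr <- paste0("early-", early_val[2 * (b - 1) + k])
      block_rows[[length(block_rows) + 1L]] <- take(tr)
    }
    for (k in 1:2) {
      tr <- paste0("late-", late_val[2 * (b - 1) + k])
      block_rows[[length(block_rows) + 1L]] <- take(tr)
    }
    block_rows[[5L]] <- take("no-social")
    block_rows[[6L]] <- take("filler")
    block <- dplyr::bind_rows(block_rows[sample.int(6)])
    block$block <- b
    rows[[b]] <- block
    idx <- idx + 6L
  }
  sched <- dplyr::bind_rows(rows)
  sched$trial_index <- seq_len(nrow(sched))

  early <- grepl("^early", sched$treatment)
  late <- grepl("^late", sched$treatment)
  social <- early | late
  nominal <- ifelse(early, config$si_onset_early_ms,
                    ifelse(late, config$si_onset_late_ms, NA_real_))
  jitter <- runif(nrow(sched), -config$jitter_ms, config$jitter_ms)
  onset <- ifelse(social, nominal + jitter, NA_real_)
  deliberation <- ifelse(sched$treatment == "filler",
                         config$filler_deliberation_ms, config$deliberation_ms)
  display <- if (config$experiment == 2) {
    ifelse(social, config$si_display_ms, NA_real_)
  } else {
    ifelse(social, deliberation - onset, NA_real_)
  }

  tibble::tibble(
    subject_id = subject_id,
    trial_index = sched$trial_index,
    block = sched$block,
    treatment = sched$treatment,
    difficulty = sched$difficulty,
    col = sched$col,
    si_validity = ifelse(social, ifelse(grepl("correct$", sched$treatment),
                                        1, -1), NA_real_),
    si_onset_ms = onset,
    si_display_ms = display,
    deliberation_ms = deliberation,
    response_window_ms = config$response_window_ms
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(list = ".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Validate a trial schedule against the design invariants
#'
#' Checks the structural constraints of the within-subject design: total
#' trial count, per-treatment counts, within-block composition, onset jitter
#' bounds, difficulty-by-color balance within treatments, and the 70%
#' accuracy of the social information.
#'
#' @param schedule A schedule tibble from [build_trial_schedule()] (a single
#'   subject's, or any table with the same columns).
#' @param jitter_ms Allowed half-width of onset jitter (ms).
#' @return A tibble with one row per check: `check`, `required`, `observed`,
#'   `pass`. Failures are reported, never raised.
#' @export
validate_schedule <- function(schedule, jitter_ms = 250) {
  stopifnot(nrow(schedule) > 0)
  assert_columns(schedule, c("trial_index", "block", "treatment",
                             "difficulty", "col"), "schedule")
  nb <- length(unique(schedule$block))
  counts <- treatment_counts(nb)
  obs <- table(factor(schedule$treatment, levels = treatment_levels()))

  checks <- list()
  add <- function(check, required, observed) {
    checks[[length(checks) + 1L]] <<- tibble::tibble(
      check = check, required = required, observed = observed,
      pass = isTRUE(all.equal(required, observed, tolerance = 1e-9)))
  }

  add("n_trials", 6 * nb, nrow(schedule))
  for (tr in treatment_levels()) {
    add(paste0("n_", tr), unname(counts[[tr]]), as.numeric(obs[[tr]]))
  }
  # within-block composition: 2 early, 2 late, 1 no-social, 1 filler
  comp <- schedule |>
    dplyr::mutate(slot = dplyr::case_when(
      grepl("^early", .data$treatment) ~ "early",
      grepl("^late", .data$treatment) ~ "late",
      TRUE ~ .data$treatment)) |>
    dplyr::count(.data$block, .data$slot)
  want <- c(early = 2, late = 2, `no-social` = 1, filler = 1)
  ok <- all(vapply(names(want), function(s) {
    v <- comp$n[comp$slot == s]
    length(v) == nb && all(v == want[[s]])
  }, TRUE))
  add("block_composition", 1, as.numeric(ok))

  # jitter bound around the nominal onsets
  if ("si_onset_ms" %in% names(schedule)) {
    social <- !is.na(schedule$si_onset_ms)
    nominal <- ifelse(grepl("^early", schedule$treatment[social]), 750, 3250)
    dev <- abs(schedule$si_onset_ms[social] - nominal)
    add("max_onset_jitter_ok", 1,
        as.numeric(length(dev) == 0 || max(dev) <= jitter_ms + 1e-9))
  }

  # difficulty x color balance within every treatment
  bal <- schedule |>
    dplyr::count(.data$treatment, .data$difficulty, .data$col) |>
    dplyr::group_by(.data$treatment) |>
    dplyr::summarise(balanced = dplyr::n() == 4 && max(.data$n) == min(.data$n),
                     .groups = "drop")
  add("cell_balance", 1, as.numeric(all(bal$balanced)))

  # social information accuracy (share of correct among social trials)
  if ("si_validity" %in% names(schedule)) {
    v <- schedule$si_validity[!is.na(schedule$si_validity)]
    add("si_accuracy", 0.70, mean(v == 1))
  }

  dplyr::bind_rows(checks)
}

#' Write or read a schedule as CSV
#'
#' @param schedule Schedule tibble.
#' @param path File path.
#' @return `read_schedule()` returns the schedule tibble;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(schedule, path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
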