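test_that("the scoring rule reproduces its defining cases", {
  expect_equal(score_judgment(1, 1.00), 25)
  expect_equal(score_judgment(1, 0.50), 0)
  expect_equal(score_judgment(0, 0.50), 0)
  expect_equal(score_judgment(0, 1.00), -75)
  expect_equal(score_judgment(NA, 0.50), 0) # undecided judgments score 0
  expect_equal(score_judgment(c(1, 0), c(0.8, 0.8)), c(21, -39))
  expect_error(score_judgment(1, 0.55), "grid")
  expect_error(score_judgment(1, 1.10), "grid")
})

test_that("the scoring rule is proper: truthful confidence maximizes expected points", {
  grid <- seq(0.5, 1, by = 0.1)
  for (p_true in c(0.52, 0.67, 0.78, 0.92, 0.98)) {
    expected <- vapply(grid, function(conf) {
      p_true * score_judgment(1, conf) + (1 - p_true) * score_judgment(0, conf)
    }, 0)
    best <- grid[which.max(expected)]
    # the optimum is the grid point nearest the true probability
    expect_equal(best, grid[which.min(abs(grid - p_true))])
  }
})

test_that("bonus payments respect the guarantee and the conversion rate", {
  expect_equal(compute_bonus(500), 1.00) # formula meets the guarantee here
  expect_equal(compute_bonus(675), 1.35)
  expect_equal(compute_bonus(0), 1.00)
  expect_equal(compute_bonus(-200), 1.00)
  expect_equal(compute_bonus(1000), 2.00)
})

test_that("exclusions match injected ground-truth labels exactly", {
  # attentive clean subjects (low latency tail) so only injected pathologies
  # trigger; see the methods vignette for this fixture's rationale
  pop <- population_spec(n_subjects = 8, mean_latency_s = 0.9,
                         sdlog_latency = 0.35)
  sim <- simulate_experiment(pop, design_config(seed = 51), seed = 52)
  spec <- tibble::tibble(subject_id = c(2, 4, 6, 8),
                         pathology = c("always-100", "below-chance",
                                       "chronic-late", "miscalibrated"))
  out <- inject_exclusion_pathologies(sim$data, spec, seed = 53)
  res <- apply_subject_exclusions(out$data)
  excluded <- res$report$subject_id[res$report$excluded]
  expect_setequal(excluded, spec$subject_id)
  # each pathological subject triggers (at least) its designated reason
  for (k in seq_len(nrow(out$labels))) {
    row <- res$report[res$report$subject_id == out$labels$subject_id[k], ]
    expect_true(row[[out$labels$reason[k]]])
  }
  expect_setequal(unique(res$data$subject_id), c(1, 3, 5, 7))
})

test_that("a clean mid-range dataset yields zero exclusions", {
  pop <- population_spec(n_subjects = 6, mean_latency_s = 0.9,
                         sdlog_latency = 0.35)
  sim <- simulate_experiment(pop, design_config(seed = 61), seed = 62)
  res <- apply_subject_exclusions(sim$data)
  expect_equal(sum(res$report$excluded), 0)
  expect_equal(nrow(res$data), nrow(sim$data))
})

test_that("exclusion is monotone in violating trials", {
  pop <- population_spec(n_subjects = 2, mean_latency_s = 0.9,
                         sdlog_latency = 0.35)
  sim <- simulate_experiment(pop, design_config(seed = 71), seed = 72)
  out <- inject_exclusion_pathologies(
    sim$data, tibble::tibble(subject_id = 1, pathology = "chronic-late"),
    seed = 73)
  base <- apply_subject_exclusions(out$data)
  expect_true(base$report$excluded[base$report$subject_id == 1])
  # adding one more violating (late) trial can never rescue the subject
  extra <- out$data[out$data$subject_id == 1, ][1, ]
  extra$late_flag <- TRUE
  extra$latency_s <- extra$response_window_ms / 1000 + 0.5
  more <- apply_subject_exclusions(dplyr::bind_rows(out$data, extra))
  expect_true(more$report$excluded[more$report$subject_id == 1])
})

test_that("trial filters implement each analysis contract and are idempotent", {
  sim <- make_test_dataset(n_subjects = 3, seed = 81)
  d <- sim$data
  acc <- apply_trial_filters(d, "accuracy")
  expect_false(any(acc$filler))
  expect_false(any(acc$confidence_category == 6))
  fit <- apply_trial_filters(d, "accumulation")
  expect_false(any(fit$filler) || any(fit$late_flag))
  ordinal <- apply_trial_filters(d, "ordinal")
  expect_equal(nrow(ordinal), sum(!d$filler))
  # idempotent
  expect_equal(apply_trial_filters(acc, "accuracy"), acc)
  expect_equal(apply_trial_filters(fit, "accumulation"), fit)
  # a filler-only dataset empties out under every analysis
  filler_only <- dplyr::filter(d, .data$filler)
  for (a in c("accuracy", "accumulation", "ordinal")) {
    expect_equal(nrow(apply_trial_filters(filler_only, a)), 0)
  }
  expect_error(apply_trial_filters(d, "anova"))
})

test_that("accuracy summaries use subjects as the unit of analysis", {
  d <- tibble::tibble(subject_id = rep(1:2, each = 4),
                      correct = 1, filler = FALSE,
                      confidence_category = 8L, late_flag = FALSE)
  s <- summarize_accuracy(d)
  expect_equal(s$mean_accuracy, 1)
  expect_equal(s$se, 0)
  # two identical subjects: zero standard error
  d2 <- dplyr::mutate(d, correct = rep(c(1, 0, 1, 1), 2))
  s2 <- summarize_accuracy(d2)
  expect_equal(s2$se, 0)
  expect_equal(s2$mean_accuracy, 0.75)
})
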