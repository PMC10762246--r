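test_that("the SDT design codes stimuli and conditions deterministically", {
  sim <- make_test_dataset(n_subjects = 2, seed = 181)
  design <- build_sdt_design(apply_trial_filters(sim$data, "ordinal"))
  # 120 trials per subject minus 20 fillers
  expect_equal(nrow(design), 2 * 100)
  expect_true(all(design$s[design$col == 1] == 0.5))
  expect_true(all(design$s[design$col == -1] == -0.5))
  expect_setequal(levels(design$condition),
                  c("absent", "early-correct", "late-correct", "early-wrong",
                    "late-wrong"))
  expect_equal(mean(design$trial_z), 0, tolerance = 1e-9)
  expect_error(build_sdt_design(sim$data), "filler")
  const <- dplyr::mutate(apply_trial_filters(sim$data, "ordinal"),
                         trial_index = 7)
  expect_error(build_sdt_design(const), "undefined")
})

test_that("the ordered probit recovers a known discrimination ability", {
  d <- simulate_sdt_data(n_subjects = 10, n_trials = 150, dprime = 1.4,
                         seed = 19)
  fit <- fit_ordered_probit(d, tiny_sampler(chains = 2, iter = 800,
                                            warmup = 300), seed = 11)
  td <- tidy(fit)
  dp <- td[td$term == "d_prime", ]
  # independent oracle: maximum-likelihood ordered probit with fixed
  # subject effects agrees with the posterior on this dataset
  ml <- MASS::polr(factor(confidence_category, levels = 1:11) ~ s + subj,
                   data = dplyr::mutate(d, subj = factor(subject_id)),
                   method = "probit")
  expect_equal(dp$estimate, unname(coef(ml)[["s"]]), tolerance = 0.05)
  # and the posterior interval is consistent with the generating value
  expect_lt(dp$conf.low, 1.4 + 3 * dp$std.error)
  expect_gt(dp$conf.high, 1.4 - 3 * dp$std.error)
  # condition effects were not simulated and stay near zero
  dd <- td[grepl("^dd_early", td$term), ]
  expect_true(all(abs(dd$estimate) < 0.5))
})

test_that("responses unrelated to the stimulus give d-prime near zero", {
  d <- simulate_sdt_data(n_subjects = 6, n_trials = 120, dprime = 0,
                         seed = 21)
  fit <- fit_ordered_probit(d, tiny_sampler(iter = 500, warmup = 200),
                            seed = 12)
  dp <- tidy(fit)[tidy(fit)$term == "d_prime", ]
  expect_gt(0, dp$conf.low)
  expect_lt(0, dp$conf.high)
})

test_that("contrast tables degenerate correctly and report evidence ratios", {
  d <- simulate_sdt_data(n_subjects = 4, n_trials = 60, dprime = 1, seed = 22)
  fit <- fit_ordered_probit(d, tiny_sampler(iter = 300, warmup = 120),
                            seed = 13)
  # force identical condition draws: all contrasts collapse to zero
  fit$draws$dd_early_correct <- fit$draws$dd_late_correct
  fit$draws$dd_early_wrong <- fit$draws$dd_late_wrong
  ct <- suppressWarnings(dprime_contrasts(fit))
  expect_equal(ct$estimate[ct$contrast == "early_minus_late_correct"], 0)
  expect_equal(ct$estimate[ct$contrast == "early_minus_late_wrong"], 0)
  expect_true(all(c("direction", "er") %in% names(ct)))
  expect_equal(nrow(ct), 10)
})

test_that("posterior predictive confidence distributions are proper", {
  sim <- make_test_dataset(n_subjects = 4, seed = 191)
  design <- build_sdt_design(apply_trial_filters(sim$data, "ordinal"))
  fit <- fit_ordered_probit(design, tiny_sampler(iter = 400, warmup = 150),
                            seed = 14)
  pp <- posterior_predictive_confidence(fit, design, n_draws = 50)
  sums <- pp |>
    dplyr::group_by(treatment) |>
    dplyr::summarise(total = sum(proportion))
  expect_true(all(abs(sums$total - 1) < 1e-9))
  expect_equal(nrow(pp), 5 * 11)
  # more high-confidence-correct mass for early-correct than late-correct
  hi <- function(tr) sum(pp$proportion[pp$treatment == tr & pp$category >= 9])
  expect_gt(hi("early-correct"), hi("no-social"))
})

test_that("binary probit recovers the direction of social-information effects", {
  sim <- make_test_dataset(n_subjects = 8, seed = 201)
  fit <- fit_binary_probit(sim$data, "validity",
                           tiny_sampler(iter = 500, warmup = 200), seed = 15)
  td <- tidy(fit)
  expect_gt(td$estimate[td$term == "si_correct"], 0)
  expect_lt(td$estimate[td$term == "si_wrong"], 0)
  pres <- fit_binary_probit(sim$data, "presence",
                            tiny_sampler(iter = 500, warmup = 200), seed = 15)
  expect_true("si_present" %in% tidy(pres)$term)
  # single-class accuracy is rejected
  allright <- dplyr::mutate(sim$data,
                            confidence_category = ifelse(col == 1, 11L, 1L))
  allright <- socialdrift:::finalize_judgments(allright)
  expect_error(fit_binary_probit(allright, "validity"), "single class")
})
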