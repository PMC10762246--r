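test_that("subject parameters follow the population distribution", {
  # degenerate hierarchy: zero spreads give every subject the population mean
  pop0 <- population_spec(n_subjects = 5, sd_delta_easy = 0, sd_delta_hard = 0,
                          sd_delta_s = 0, sd_gamma = 0, sd_tau = 0)
  par0 <- draw_subject_parameters(pop0, seed = 1)
  expect_true(all(par0$delta_easy == 0.90))
  expect_true(all(par0$gamma == 2.41))
  # at the Experiment-1 point estimates, sample means approach the truth
  pop <- population_spec(n_subjects = 1e4)
  par <- draw_subject_parameters(pop, seed = 2)
  expect_equal(mean(par$delta_s), 0.18, tolerance = 0.05)
  expect_equal(mean(par$gamma), 2.41, tolerance = 0.02)
  expect_equal(mean(par$delta_easy), 0.90, tolerance = 0.02)
  # bit-identical under a fixed seed
  expect_identical(par, draw_subject_parameters(pop, seed = 2))
  expect_error(population_spec(criteria_increments = c(1, 1, -1, 1, 1)),
               "positive")
})

test_that("a null generator produces judgments symmetric about the 50% category", {
  sched <- flat_schedule(1e5)
  params <- tibble::tibble(subject_id = 1L, delta_easy = 0, delta_hard = 0,
                           delta_s = 0, gamma = 0, tau = 0)
  attr(params, "criteria") <- make_criteria(rep(0.6, 5))
  data <- simulate_dataset(sched, params, frozen_latency_pop(), seed = 3)
  freq <- tabulate(data$confidence_category, 11) / nrow(data)
  p_exp <- category_probabilities(0, mean(data$dt_s), attr(params, "criteria"))
  se <- sqrt(colMeans(p_exp) * (1 - colMeans(p_exp)) / nrow(data))
  expect_true(all(abs(freq - rev(freq)) < 6 * se))
})

test_that("correct social information raises accuracy and wrong lowers it", {
  sim <- make_test_dataset(n_subjects = 12, seed = 21)
  acc <- apply_trial_filters(sim$data, "accuracy") |>
    dplyr::mutate(si = dplyr::case_when(is.na(si_validity) ~ "absent",
                                        si_validity == 1 ~ "correct",
                                        TRUE ~ "wrong")) |>
    summarize_accuracy(si)
  a <- setNames(acc$mean_accuracy, acc$si)
  expect_gt(a[["correct"]], a[["absent"]])
  expect_gt(a[["absent"]], a[["wrong"]])
})

test_that("with a social drift, early social information sways judgments more", {
  params <- tibble::tibble(subject_id = 1L, delta_easy = 0, delta_hard = 0,
                           delta_s = 0.18, gamma = 0, tau = 0)
  attr(params, "criteria") <- make_criteria(rep(1.75, 5))
  pop <- frozen_latency_pop()
  n <- 1e5
  early <- simulate_dataset(flat_schedule(n, si_validity = 1, st_s = 3.25),
                            params, pop, seed = 4)
  late <- simulate_dataset(flat_schedule(n, si_validity = 1, st_s = 0.75),
                           params, pop, seed = 5)
  # signed confidence toward the socially indicated option (orange here)
  signed <- function(d) mean(d$reported * d$confidence)
  expect_gt(signed(early), signed(late))
  # oracle: the closed-form mean difference is delta_s * (ST_early - ST_late)
  m_e <- trial_moments(early[1, ], accumulator_parameters(
    delta_easy = 0, delta_hard = 0, delta_s = 0.18, gamma = 0, tau = 0))
  m_l <- trial_moments(late[1, ], accumulator_parameters(
    delta_easy = 0, delta_hard = 0, delta_s = 0.18, gamma = 0, tau = 0))
  expect_equal(m_e$mean_color - m_l$mean_color,
               0.18 * (early$st_s[1] - late$st_s[1]))
  expect_equal(early$st_s[1] - late$st_s[1], 3.25 - 0.75, tolerance = 1e-3)
})

test_that("a pure shift predicts no timing effect; a drift predicts a graded one", {
  # shift only: identical category distributions for early vs late
  p_shift <- function(st) {
    params <- accumulator_parameters(delta_easy = 0.5, delta_hard = 0.25,
                                     delta_s = 0, gamma = 2, tau = 0)
    mom <- trial_moments(
      dplyr::mutate(flat_schedule(1, si_validity = 1, st_s = st), dummy = 1),
      params)
    category_probabilities(mom$mean_color, mom$var, params$criteria)
  }
  expect_lt(max(abs(p_shift(4.35) - p_shift(1.85))), 1e-12)
  # drift: P(report the socially indicated option) increases with ST
  params <- tibble::tibble(subject_id = 1L, delta_easy = 0, delta_hard = 0,
                           delta_s = 0.3, gamma = 0, tau = 0)
  attr(params, "criteria") <- make_criteria(rep(1.75, 5))
  pop <- frozen_latency_pop()
  p_si <- vapply(c(0.5, 2, 3.5), function(st) {
    d <- simulate_dataset(flat_schedule(3e4, si_validity = 1, st_s = st),
                          params, pop, seed = 6)
    mean(d$reported == 1)
  }, 0)
  expect_true(all(diff(p_si) > 0))
})

test_that("simulated frequencies match the likelihood's category probabilities", {
  set.seed(8)
  for (rep in 1:3) {
    params <- tibble::tibble(subject_id = 1L,
                             delta_easy = runif(1, -0.5, 1),
                             delta_hard = runif(1, -0.5, 1),
                             delta_s = runif(1, 0, 0.4),
                             gamma = runif(1, 0, 3), tau = runif(1, -1, 1))
    crit <- make_criteria(runif(5, 0.5, 2))
    attr(params, "criteria") <- crit
    sched <- flat_schedule(1e5, si_validity = sample(c(1, -1), 1), st_s = 3)
    d <- simulate_dataset(sched, params, frozen_latency_pop(),
                          seed = 80 + rep)
    ap <- accumulator_parameters(params$delta_easy, params$delta_hard,
                                 params$delta_s, params$gamma, params$tau,
                                 criteria = crit)
    mom <- trial_moments(d[1, ], ap)
    p <- as.numeric(category_probabilities(mom$mean_color, mom$var, crit))
    freq <- tabulate(d$confidence_category, 11) / nrow(d)
    se <- sqrt(pmax(p * (1 - p), 1e-12) / nrow(d))
    expect_true(all(abs(freq - p) < 3 * se + 1e-4))
  }
})

test_that("pathology injection produces the targeted violations", {
  sim <- make_test_dataset(n_subjects = 6, seed = 31)
  spec <- tibble::tibble(subject_id = 1:4,
                         pathology = c("always-100", "below-chance",
                                       "chronic-late", "miscalibrated"))
  out <- inject_exclusion_pathologies(sim$data, spec, seed = 32)
  d <- out$data
  s1 <- d[d$subject_id == 1, ]
  expect_gt(mean(s1$confidence_category %in% c(1, 11)), 0.90)
  s2 <- d[d$subject_id == 2, ]
  expect_lt(mean(s2$correct, na.rm = TRUE), 0.50)
  s3 <- d[d$subject_id == 3, ]
  expect_gt(sum(s3$late_flag), 10)
  s4 <- d[d$subject_id == 4, ]
  expect_gt(mean(s4$confidence[s4$correct == 0], na.rm = TRUE),
            mean(s4$confidence[s4$correct == 1], na.rm = TRUE))
  # empty spec leaves the data untouched; unknown names are rejected
  empty <- inject_exclusion_pathologies(sim$data, spec[0, ])
  expect_identical(empty$data, sim$data)
  expect_error(inject_exclusion_pathologies(
    sim$data, tibble::tibble(subject_id = 1, pathology = "sleepy")),
    "unknown pathology")
})

test_that("datasets round-trip through CSV", {
  sim <- make_test_dataset(n_subjects = 2, seed = 41)
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(sim$data, path)
  back <- read_dataset(path)
  expect_equal(nrow(back), nrow(sim$data))
  expect_equal(back$confidence_category, sim$data$confidence_category)
})
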