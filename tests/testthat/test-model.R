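test_that("trial moments follow the closed form", {
  # the worked social-information example: drift part 0.18 * 3.1 = 0.558
  params <- accumulator_parameters(delta_easy = 0, delta_hard = 0,
                                   delta_s = 0.18, gamma = 2.41, tau = 0)
  trial <- tibble::tibble(dt_s = 6.1, st_s = 3.1, col = 1, si_validity = 1,
                          difficulty = "easy")
  mom <- trial_moments(trial, params)
  expect_equal(mom$mean_correct, 0.18 * 3.1 + 2.41)
  expect_equal(round(0.18 * 3.1, 2), 0.56)
  # all parameters zero: mean 0, variance DT
  p0 <- accumulator_parameters(0, 0, 0, 0, 0)
  m0 <- trial_moments(tibble::tibble(dt_s = 4, st_s = 0,
                                     col = -1, si_validity = NA,
                                     difficulty = "hard"), p0)
  expect_equal(m0$mean_correct, 0)
  expect_equal(m0$var, 4)
  expect_error(trial_moments(dplyr::mutate(trial, dt_s = 0), params),
               "positive")
})

test_that("relabeling the colors mirrors the color-axis mean and probabilities", {
  params <- accumulator_parameters(delta_easy = 0.7, delta_hard = 0.3,
                                   delta_s = 0.2, gamma = 1.5, tau = 0.4)
  mirrored <- accumulator_parameters(delta_easy = 0.7, delta_hard = 0.3,
                                     delta_s = 0.2, gamma = 1.5, tau = -0.4)
  trial <- tibble::tibble(dt_s = 5.5, st_s = 2.2, col = 1, si_validity = -1,
                          difficulty = "easy")
  flipped <- dplyr::mutate(trial, col = -col)
  m1 <- trial_moments(trial, params)
  m2 <- trial_moments(flipped, mirrored)
  expect_equal(m2$mean_color, -m1$mean_color)
  p1 <- category_probabilities(m1$mean_color, m1$var, params$criteria)
  p2 <- category_probabilities(m2$mean_color, m2$var, params$criteria)
  expect_equal(as.numeric(p2), rev(as.numeric(p1)))
})

test_that("category probabilities normalize, mirror, and saturate", {
  set.seed(9)
  for (k in 1:200) {
    crit <- make_criteria(runif(5, 0.2, 2.5))
    p <- category_probabilities(runif(1, -12, 12), runif(1, 0.5, 12), crit)
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  crit <- make_criteria(rep(1, 5))
  p0 <- category_probabilities(0, 4, crit)
  expect_equal(as.numeric(p0), rev(as.numeric(p0)))
  expect_gt(category_probabilities(1e4, 4, crit)[, "p11"], 1 - 1e-12)
  expect_error(category_probabilities(0, 4, sort(runif(10)) * c(1, -1)),
               "increasing")
  expect_error(category_probabilities(0, -1, crit), "positive")
})

test_that("category probabilities match Monte-Carlo binning frequencies", {
  set.seed(10)
  for (k in 1:5) {
    crit <- make_criteria(runif(5, 0.3, 2))
    mu <- runif(1, -6, 6)
    v <- runif(1, 1, 9)
    p <- as.numeric(category_probabilities(mu, v, crit))
    n <- 1e5
    freq <- tabulate(draw_categories(n, mu, v, crit), 11) / n
    se <- sqrt(pmax(p * (1 - p), 1e-12) / n)
    expect_true(all(abs(freq - p) < 3 * se + 1e-4))
  }
})

test_that("the log-likelihood matches closed forms and is additive", {
  params <- accumulator_parameters(0, 0, 0, 0, 0,
                                   criteria = make_criteria(rep(0.8, 5)))
  one <- dplyr::mutate(flat_schedule(1), confidence_category = 6L)
  ll <- log_likelihood(one, params)
  c6 <- params$criteria[6]
  expect_equal(ll$total, log(2 * pnorm(c6 / sqrt(5)) - 1))
  # duplicating the data doubles the total
  sim <- make_test_dataset(n_subjects = 2, seed = 91)
  d <- apply_trial_filters(sim$data, "accumulation")
  p_true <- accumulator_parameters()
  ll1 <- log_likelihood(d, p_true)
  ll2 <- log_likelihood(dplyr::bind_rows(d, d), p_true)
  expect_equal(ll2$total, 2 * ll1$total)
  expect_equal(nrow(ll1$pointwise), nrow(d))
})

test_that("generating parameters outscore perturbed parameters", {
  wins <- 0
  for (rep in 1:20) {
    crit <- make_criteria(rep(1.75, 5))
    truth <- tibble::tibble(subject_id = 1L, delta_easy = 0.9,
                            delta_hard = 0.45, delta_s = 0.18, gamma = 2.41,
                            tau = 0)
    attr(truth, "criteria") <- crit
    d <- simulate_dataset(flat_schedule(1500, si_validity = 1, st_s = 3),
                          truth, population_spec(n_subjects = 1),
                          seed = 900 + rep)
    at_truth <- log_likelihood(d, accumulator_parameters())$total
    perturbed <- log_likelihood(d, accumulator_parameters(
      delta_easy = 1.35, delta_hard = 0.675, delta_s = 0.27,
      gamma = 2.41, tau = 0))$total
    wins <- wins + (at_truth >= perturbed)
  }
  expect_gte(wins, 19)
})

test_that("all eight variants are enumerated once", {
  v <- model_variants()
  expect_equal(nrow(v), 8)
  expect_equal(anyDuplicated(v$variant), 0)
  expect_true("full" %in% v$variant)
  expect_true("null" %in% v$variant)
  expect_equal(sum(v$personal_drift), 4)
})
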