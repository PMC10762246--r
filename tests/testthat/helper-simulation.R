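# shared fixtures, all generated in code

# quick sampler budgets for unit tests
tiny_sampler <- function(chains = 1, iter = 400, warmup = 150) {
  sampler_config(chains = chains, iter = iter, warmup = warmup)
}

# a flat schedule for likelihood-level tests: constant timing per condition.
# `st_s` is the time from social-information onset to the end of the
# deliberation phase; the simulated ST adds the response latency on top.
flat_schedule <- function(n_trials, col = 1, difficulty = "easy",
                          si_validity = NA_real_, st_s = 0, dt_s = 5,
                          subject_id = 1L) {
  tibble::tibble(
    subject_id = subject_id,
    trial_index = seq_len(n_trials),
    block = 1L,
    treatment = ifelse(is.na(si_validity), "no-social",
                       ifelse(st_s > 2, "early-correct", "late-correct")),
    difficulty = difficulty,
    col = col,
    si_validity = si_validity,
    si_onset_ms = ifelse(is.na(si_validity), NA_real_, 4000 - st_s * 1000),
    si_display_ms = NA_real_,
    deliberation_ms = 4000,
    response_window_ms = 2000,
    dt_s = dt_s,
    st_s = st_s
  )
}

# a latency law that is effectively a point mass, so DT and ST are constant
# across trials and single-condition closed forms apply exactly
frozen_latency_pop <- function(latency = 1.1) {
  population_spec(n_subjects = 1, mean_latency_s = latency,
                  sdlog_latency = 1e-5)
}

# draw judgments directly from given moments and criteria (bypasses the
# latency machinery); independent of the package's simulate_dataset path
draw_categories <- function(n, mean, var, criteria) {
  findInterval(rnorm(n, mean, sqrt(var)), criteria) + 1L
}

# a small multi-subject dataset at Experiment-1-like truth
make_test_dataset <- function(n_subjects = 6, seed = 1, ...) {
  pop <- population_spec(n_subjects = n_subjects, ...)
  simulate_experiment(pop, design_config(seed = seed), seed = seed + 1)
}

# ordinal data from the SDT generative model: latent mean s*dprime + subject
# intercept, unit noise, fixed symmetric thresholds
simulate_sdt_data <- function(n_subjects, n_trials, dprime, sd_subject = 0.3,
                              thresholds = c(-2.5, -1.9, -1.3, -0.7, -0.2,
                                             0.2, 0.7, 1.3, 1.9, 2.5),
                              seed = 1) {
  set.seed(seed)
  a <- rnorm(n_subjects, 0, sd_subject)
  purrr::map_dfr(seq_len(n_subjects), function(u) {
    col <- sample(c(-1, 1), n_trials, replace = TRUE)
    mu <- (col / 2) * dprime + a[u]
    y <- findInterval(rnorm(n_trials, mu, 1), thresholds) + 1L
    tibble::tibble(subject_id = u, s = col / 2,
                   condition = factor("absent",
                                      levels = socialdrift:::sdt_condition_levels()),
                   hard = 0, trial_z = rnorm(n_trials),
                   confidence_category = y, col = col,
                   treatment = "no-social",
                   correct = ifelse(y == 6L, NA,
                                    as.numeric(sign(y - 6) == col)))
  })
}
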