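#' Sampler configuration
#'
#' Chain/iteration budget and priors shared by all hierarchical fits. The
#' `"reference"` budget is the full protocol (5 chains of 5000 iterations,
#' half discarded as warmup); the `"test"` budget is a scaled-down setting
#' for simulation studies and examples.
#'
#' @param chains Number of MCMC chains.
#' @param iter Iterations per chain (including warmup).
#' @param warmup Iterations discarded per chain.
#' @param thin Keep every `thin`-th draw.
#' @param prior_loc_sd Normal prior SD for population means / regression
#'   coefficients (weakly informative, zero-centered).
#' @param prior_scale_sd Half-normal prior SD for population SDs / random
#'   intercept spread.
#' @param prior_inc_sd Half-normal prior SD for criteria and threshold
#'   increments.
#' @param budget `"reference"` or `"test"`; presets overridden by explicit
#'   arguments.
#' @return A `sampler_config` object.
#' @export
sampler_config <- function(chains = NULL, iter = NULL, warmup = NULL,
                           thin = 1, prior_loc_sd = 2, prior_scale_sd = 1,
                           prior_inc_sd = 1,
                           budget = c("test", "reference")) {
  budget <- match.arg(budget)
  preset <- switch(budget,
                   reference = list(chains = 5, iter = 5000, warmup = 2500),
                   test = list(chains = 2, iter = 900, warmup = 300))
  structure(list(
    chains = chains %||% preset$chains,
    iter = iter %||% preset$iter,
    warmup = warmup %||% preset$warmup,
    thin = thin,
    prior_loc_sd = prior_loc_sd,
    prior_scale_sd = prior_scale_sd,
    prior_inc_sd = prior_inc_sd,
    budget = budget
  ), class = "sampler_config")
}

ea_param_names <- c("delta_easy", "delta_hard", "delta_s", "gamma", "tau")

#' Fit the hierarchical evidence-accumulation model
#'
#' Samples the posterior of one shift/drift model variant: subject-level
#' personal drifts, social drift, social shift, and color bias with normal
#' population distributions, plus confidence criteria shared across
#' subjects (five positive increments, mirror-symmetric). Parameters
#' excluded by the variant are fixed at 0. Sampling uses slice-within-Gibbs
#' updates; draws are exactly reproducible given `seed` and the
#' configuration.
#'
#' @param data Judgment tibble with the accumulation filter applied
#'   (filler and late trials removed).
#' @param variant A row name from [model_variants()] (default `"full"`).
#' @param config A [sampler_config()].
#' @param seed Integer seed.
#' @param fix_scale If non-`NULL`, pins all population SDs at this value;
#'   `0` degenerates the hierarchy so all subjects share the population
#'   mean (usable with a single subject).
#' @param save_loglik Keep the draws-by-trials log-likelihood matrix
#'   (needed for [compute_looic()]).
#' @return An object of class `ea_fit`: `draws` (tibble of population-level
#'   draws with `.chain`), `theta` (draws-by-(subject x parameter) matrix),
#'   `loglik`, `diagnostics` (split-Rhat and effective sample size per
#'   population parameter), `converged` flag, and run metadata.
#' @export
fit_accumulator <- function(data, variant = "full",
                            config = sampler_config(), seed = 1,
                            fix_scale = NULL, save_loglik = TRUE) {
  stopifnot(inherits(config, "sampler_config"))
  assert_columns(data, c("subject_id", "confidence_category", "col",
                         "difficulty", "dt_s", "st_s", "si_validity"))
  variants <- model_variants()
  if (!variant %in% variants$variant) {
    stop("unknown variant: ", variant)
  }
  v <- variants[variants$variant == variant, ]
  subjects <- sort(unique(data$subject_id))
  if (length(subjects) < 2 && is.null(fix_scale)) {
    stop("at least 2 subjects are required unless `fix_scale` is given")
  }
  si <- as.numeric(!is.na(data$si_validity))
  ssign <- ifelse(si == 1, data$col * data$si_validity, 0)
  use <- c(v$personal_drift, v$personal_drift, v$social_drift,
           v$social_shift)

  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    chains[[ch]] <- ea_mcmc_cpp(
      y = as.integer(data$confidence_category),
      subj = match(data$subject_id, subjects) - 1L,
      col = as.numeric(data$col),
      hard = as.integer(data$difficulty == "hard"),
      DT = data$dt_s, ST = ifelse(si == 1, data$st_s, 0), ssign = ssign,
      n_subj = length(subjects), use = use,
      iter = config$iter, warmup = config$warmup, thin = config$thin,
      prior_loc_sd = config$prior_loc_sd,
      prior_scale_sd = config$prior_scale_sd,
      prior_inc_sd = config$prior_inc_sd,
      fixed_scale = fix_scale %||% -1,
      save_loglik = save_loglik)
  }

  per_chain <- nrow(chains[[1]]$pop_mean)
  draws <- purrr::imap_dfr(chains, function(cc, ch) {
    pm <- cc$pop_mean
    ps <- cc$pop_sd
    colnames(pm) <- paste0("mu_", ea_param_names)
    colnames(ps) <- paste0("sd_", ea_param_names)
    crit <- t(apply(cc$inc, 1, make_criteria))
    colnames(crit) <- paste0("c", 1:10)
    dplyr::bind_cols(tibble::tibble(.chain = ch,
                                    .iteration = seq_len(per_chain)),
                     tibble::as_tibble(pm), tibble::as_tibble(ps),
                     tibble::as_tibble(crit))
  })
  theta <- do.call(rbind, lapply(chains, `[[`, "theta"))
  colnames(theta) <- paste(rep(ea_param_names, times = length(subjects)),
                           rep(subjects, each = 5), sep = ".")
  loglik <- if (save_loglik) {
    do.call(rbind, lapply(chains, `[[`, "loglik"))
  } else NULL

  monitored <- c(paste0("mu_", ea_param_names[use_mask(use)]),
                 paste0("c", 6:10))
  diagnostics <- fit_diagnostics(draws, monitored)
  structure(list(
    draws = draws, theta = theta, loglik = loglik,
    diagnostics = diagnostics,
    converged = all(is.finite(diagnostics$rhat)) &&
      max(diagnostics$rhat) <= 1.05,
    variant = variant, use = use, subjects = subjects,
    n_trials = nrow(data), config = config, seed = seed,
    fix_scale = fix_scale
  ), class = "ea_fit")
}

use_mask <- function(use) c(use[1], use[2], use[3], use[4], TRUE)

fit_diagnostics <- function(draws, params) {
  purrr::map_dfr(params, function(p) {
    x <- draws[[p]]
    tibble::tibble(parameter = p,
                   rhat = split_rhat(x, draws$.chain),
                   ess = ess_of(x, draws$.chain))
  })
}

#' @export
print.ea_fit <- function(x, ...) {
  cat(sprintf("hierarchical accumulator fit: variant '%s', %d subjects, %d trials\n",
              x$variant, length(x$subjects), x$n_trials))
  cat(sprintf("%d chains x %d post-warmup draws; max Rhat %.3f (%s)\n",
              x$config$chains, nrow(x$draws) / x$config$chains,
              max(x$diagnostics$rhat, na.rm = TRUE),
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @rdname tidy.ea_fit
#' @method glance ea_fit
#' @export
glance.ea_fit <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 n_subjects = length(x$subjects),
                 n_trials = x$n_trials,
                 n_draws = nrow(x$draws),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' Tidy posterior summaries of a fitted model
#'
#' @param x An `ea_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`/`conf.high` (central 95% interval), and,
#'   where monitored, `rhat` and `ess`.
#' @method tidy ea_fit
#' @export
tidy.ea_fit <- function(x, ...) {
  terms <- setdiff(names(x$draws), c(".chain", ".iteration"))
  out <- purrr::map_dfr(terms, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
  dplyr::left_join(out, x$diagnostics, by = c(term = "parameter"))
}

#' Posterior means of subject-level parameters
#'
#' @param fit An `ea_fit`.
#' @return A tibble with one row per subject and one column per parameter.
#' @export
subject_estimates <- function(fit) {
  stopifnot(inherits(fit, "ea_fit"))
  est <- colMeans(fit$theta)
  parts <- strsplit(names(est), ".", fixed = TRUE)
  tibble::tibble(
    subject_id = as.integer(vapply(parts, `[`, "", 2)),
    parameter = vapply(parts, `[`, "", 1),
    estimate = unname(est)
  ) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "estimate")
}

#' Compare the eight model variants by LOOIC
#'
#' Fits every variant to the same dataset with the same sampler budget and
#' ranks them by PSIS-LOO information criterion (lower is better). A
#' variant whose fit fails is ranked last and flagged.
#'
#' @param data Judgment tibble (accumulation filter applied).
#' @param variants Tibble as from [model_variants()].
#' @param config A [sampler_config()].
#' @param seed Integer seed (shared across variants).
#' @return A tibble: `variant`, `looic`, `se`, `p_loo`, `n_high_k`,
#'   `converged`, `failed`, `rank`.
#' @export
compare_variants <- function(data, variants = model_variants(),
                             config = sampler_config(), seed = 1) {
  rows <- purrr::map_dfr(variants$variant, function(vn) {
    fit <- tryCatch(fit_accumulator(data, vn, config = config, seed = seed),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      return(tibble::tibble(variant = vn, looic = NA_real_, se = NA_real_,
                            p_loo = NA_real_, n_high_k = NA_integer_,
                            converged = FALSE, failed = TRUE))
    }
    loo <- compute_looic(fit)
    tibble::tibble(variant = vn, looic = loo$looic, se = loo$se,
                   p_loo = loo$p_loo, n_high_k = loo$n_high_k,
                   converged = fit$converged, failed = FALSE)
  })
  rows$rank <- rank(ifelse(rows$failed, Inf, rows$looic),
                    ties.method = "first")
  dplyr::arrange(rows, .data$rank)
}

#' Evidence ratio for a directional hypothesis
#'
#' Ratio of posterior draws compatible with the hypothesized direction to
#' those incompatible. By convention, ratios between 1 and 3.2 are weak,
#' between 3.2 and 20 substantial, and above 20 strong evidence; when all
#' draws are compatible the ratio is reported capped at the number of
#' draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param direction `"+"` (effect > 0) or `"-"`.
#' @return The evidence ratio (capped at `length(draws)`).
#' @export
evidence_ratio <- function(draws, direction = c("+", "-")) {
  direction <- match.arg(direction)
  if (length(draws) == 0) stop("at least one draw is required")
  n_for <- if (direction == "+") sum(draws > 0) else sum(draws < 0)
  n_against <- length(draws) - n_for
  if (n_against == 0) return(length(draws))
  n_for / n_against
}

#' @rdname evidence_ratio
#' @export
er_category <- function(er) {
  cut(er, c(-Inf, 1, 3.2, 20, Inf),
      labels = c("opposing", "weak", "substantial", "strong"))
}

#' Parameter recovery study
#'
#' Simulates datasets at a known population truth, refits the full model,
#' and quantifies recovery: the correlation between true and estimated
#' subject-level parameters, and coverage of the population means by the
#' posterior 95% intervals.
#'
#' @param pop A [population_spec()] (the truth).
#' @param design_cfg A [design_config()].
#' @param n_replicates Number of simulated datasets.
#' @param config A [sampler_config()].
#' @param seed Integer seed.
#' @param variant Variant to fit (default `"full"`).
#' @return An `ea_recovery` object: `results` (per replicate and parameter:
#'   correlation, population-mean coverage), `subject_pairs` (true vs
#'   estimated subject values, plot-ready), and `n_failed`.
#' @export
parameter_recovery <- function(pop, design_cfg = design_config(),
                               n_replicates = 1,
                               config = sampler_config(), seed = 1,
                               variant = "full") {
  results <- list()
  pairs <- list()
  n_failed <- 0L
  truth_means <- c(delta_easy = pop$mean_delta_easy,
                   delta_hard = pop$mean_delta_hard,
                   delta_s = pop$mean_delta_s,
                   gamma = pop$mean_gamma, tau = pop$mean_tau)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_experiment(pop, design_cfg, seed = seed + 131L * r)
    fitted <- apply_trial_filters(sim$data, "accumulation")
    fit <- tryCatch(
      fit_accumulator(fitted, variant, config = config,
                      seed = seed + 131L * r),
      error = function(e) e)
    if (inherits(fit, "error") || !fit$converged) {
      # non-converged replicates are excluded from the summaries and counted
      n_failed <- n_failed + 1L
      next
    }
    est <- subject_estimates(fit)
    truth <- sim$subject_params
    for (p in ea_param_names) {
      mu_draws <- fit$draws[[paste0("mu_", p)]]
      ci <- quantile(mu_draws, c(0.025, 0.975))
      results[[length(results) + 1L]] <- tibble::tibble(
        replicate = r, parameter = p,
        correlation = cor(truth[[p]], est[[p]]),
        true_pop_mean = unname(truth_means[p]),
        post_mean = mean(mu_draws),
        lower = unname(ci[1]), upper = unname(ci[2]),
        covered = truth_means[p] >= ci[1] & truth_means[p] <= ci[2],
        converged = fit$converged)
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        replicate = r, parameter = p, subject_id = truth$subject_id,
        true = truth[[p]], estimated = est[[p]])
    }
  }
  structure(list(results = dplyr::bind_rows(results),
                 subject_pairs = dplyr::bind_rows(pairs),
                 n_failed = n_failed),
            class = "ea_recovery")
}

#' @export
print.ea_recovery <- function(x, ...) {
  cat("parameter recovery summary\n")
  print(tidy.ea_recovery(x))
  invisible(x)
}

#' @rdname parameter_recovery
#' @param x An `ea_recovery`.
#' @param ... Unused.
#' @method tidy ea_recovery
#' @export
tidy.ea_recovery <- function(x, ...) {
  if (nrow(x$results) == 0) {
    return(tibble::tibble(parameter = character(),
                          mean_correlation = numeric(),
                          coverage = numeric(), n_replicates = integer()))
  }
  x$results |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(mean_correlation = mean(.data$correlation),
                     coverage = mean(.data$covered),
                     n_replicates = dplyr::n(), .groups = "drop")
}
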