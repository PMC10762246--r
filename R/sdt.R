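sdt_condition_levels <- function() {
  c("absent", "early-correct", "late-correct", "early-wrong", "late-wrong")
}

#' Design table for the signal-detection analyses
#'
#' Builds the ordinal-regression design from a judgment dataset: stimulus
#' code `s = col/2` (+0.5 orange, -0.5 blue) so that its coefficient is the
#' discrimination ability d-prime, a five-level social-information
#' condition (absent and timing-by-validity), a hard-trial indicator, and
#' the z-scored trial number. Filler trials must already be removed (use
#' [apply_trial_filters()] with `"ordinal"`).
#'
#' @param data Judgment tibble without filler trials.
#' @return A tibble: `subject_id`, `s`, `condition`, `hard`, `trial_z`,
#'   `confidence_category`, `col`, `treatment`, `correct`.
#' @export
build_sdt_design <- function(data) {
  assert_columns(data, c("subject_id", "treatment", "col", "difficulty",
                         "trial_index", "confidence_category"))
  if (any(data$treatment == "filler")) {
    stop("filler trials must be removed before building the design")
  }
  bad <- setdiff(unique(data$treatment), treatment_levels())
  if (length(bad) > 0) stop("unknown treatment label(s): ",
                            paste(bad, collapse = ", "))
  if (sd(data$trial_index) == 0) {
    stop("trial numbers are constant; the z-scored trial predictor is undefined")
  }
  tibble::tibble(
    subject_id = data$subject_id,
    s = data$col / 2,
    condition = factor(ifelse(data$treatment == "no-social", "absent",
                              data$treatment),
                       levels = sdt_condition_levels()),
    hard = as.numeric(data$difficulty == "hard"),
    trial_z = as.numeric(scale(data$trial_index)),
    confidence_category = data$confidence_category,
    col = data$col,
    treatment = data$treatment,
    correct = data$correct
  )
}

sdt_term_names <- c("d_prime", "dd_early_correct", "dd_late_correct",
                    "dd_early_wrong", "dd_late_wrong", "dd_hard", "dd_trial")

#' Ordered-probit regression of the 11-point judgment
#'
#' Fits the Bayesian signal-detection model: the latent judgment mean is
#' `s * (d' + sum of condition/difficulty/trial effects) + subject
#' intercept` with unit latent noise, cut by ten estimated thresholds into
#' the 11 confidence categories. Condition effects enter only in
#' interaction with the stimulus code, so they are changes in
#' discrimination ability (delta d-prime).
#'
#' @param design Tibble from [build_sdt_design()].
#' @param config A [sampler_config()].
#' @param seed Integer seed.
#' @return An `sdt_fit`: `draws` (tibble of d-prime terms, thresholds,
#'   random-intercept spread, with `.chain`), `ranef`, `loglik`,
#'   `diagnostics`, `converged`, and metadata.
#' @export
fit_ordered_probit <- function(design, config = sampler_config(), seed = 1) {
  assert_columns(design, c("subject_id", "s", "condition", "hard",
                           "trial_z", "confidence_category"), "design")
  subjects <- sort(unique(design$subject_id))
  if (length(subjects) < 2) stop("at least 2 subjects are required")
  cond <- design$condition
  X <- cbind(1,
             cond == "early-correct", cond == "late-correct",
             cond == "early-wrong", cond == "late-wrong",
             design$hard, design$trial_z) * design$s
  colnames(X) <- sdt_term_names
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    chains[[ch]] <- op_mcmc_cpp(
      y = as.integer(design$confidence_category), X = X,
      subj = match(design$subject_id, subjects) - 1L,
      n_subj = length(subjects), K = 11L,
      iter = config$iter, warmup = config$warmup, thin = config$thin,
      prior_beta_sd = config$prior_loc_sd, prior_t_sd = config$prior_loc_sd,
      prior_inc_sd = config$prior_inc_sd,
      prior_ranef_sd = config$prior_scale_sd, save_loglik = TRUE)
  }
  per_chain <- nrow(chains[[1]]$beta)
  draws <- purrr::imap_dfr(chains, function(cc, ch) {
    b <- cc$beta
    colnames(b) <- sdt_term_names
    th <- cc$thresholds
    colnames(th) <- paste0("t", 1:10)
    dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iteration = seq_len(per_chain)),
      tibble::as_tibble(b), tibble::as_tibble(th),
      tibble::tibble(sd_subject = as.numeric(cc$sd_ranef)))
  })
  ranef <- do.call(rbind, lapply(chains, `[[`, "ranef"))
  colnames(ranef) <- as.character(subjects)
  loglik <- do.call(rbind, lapply(chains, `[[`, "loglik"))
  diagnostics <- fit_diagnostics(draws, sdt_term_names)
  structure(list(draws = draws, ranef = ranef, loglik = loglik,
                 diagnostics = diagnostics,
                 converged = all(is.finite(diagnostics$rhat)) &&
                   max(diagnostics$rhat) <= 1.05,
                 subjects = subjects, n_trials = nrow(design),
                 config = config, seed = seed),
            class = "sdt_fit")
}

#' @export
print.sdt_fit <- function(x, ...) {
  cat(sprintf("ordered-probit SDT fit: %d subjects, %d trials, max Rhat %.3f\n",
              length(x$subjects), x$n_trials,
              max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

#' @rdname dprime_contrasts
#' @method tidy sdt_fit
#' @export
tidy.sdt_fit <- function(x, ...) {
  terms <- setdiff(names(x$draws), c(".chain", ".iteration"))
  out <- purrr::map_dfr(terms, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
  dplyr::left_join(out, x$diagnostics, by = c(term = "parameter"))
}

#' @method glance sdt_fit
#' @export
glance.sdt_fit <- function(x, ...) {
  tibble::tibble(n_subjects = length(x$subjects), n_trials = x$n_trials,
                 n_draws = nrow(x$draws),
                 max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
                 converged = x$converged)
}

#' Discrimination-ability contrasts with evidence ratios
#'
#' Summarizes the condition effects of an ordered-probit SDT fit: each
#' delta d-prime against zero, the early-minus-late timing contrasts within
#' correct and within wrong social information, the correct-vs-wrong
#' magnitude comparisons within each timing, and the timing-symmetry
#' contrast. Each directional hypothesis gets an evidence ratio.
#'
#' @param fit An `sdt_fit`.
#' @return A tibble: `contrast`, `estimate`, `conf.low`, `conf.high`,
#'   `direction` (hypothesized sign), `er`.
#' @export
dprime_contrasts <- function(fit) {
  stopifnot(inherits(fit, "sdt_fit"))
  if (!fit$converged) {
    warning("contrasts computed from a non-converged fit")
  }
  d <- fit$draws
  contrasts <- list(
    d_prime = list(d$d_prime, "+"),
    dd_early_correct = list(d$dd_early_correct, "+"),
    dd_late_correct = list(d$dd_late_correct, "+"),
    dd_early_wrong = list(d$dd_early_wrong, "-"),
    dd_late_wrong = list(d$dd_late_wrong, "-"),
    early_minus_late_correct = list(d$dd_early_correct - d$dd_late_correct,
                                    "+"),
    early_minus_late_wrong = list(d$dd_early_wrong - d$dd_late_wrong, "-"),
    abs_correct_minus_wrong_early = list(abs(d$dd_early_correct) -
                                           abs(d$dd_early_wrong), "+"),
    abs_correct_minus_wrong_late = list(abs(d$dd_late_correct) -
                                          abs(d$dd_late_wrong), "+"),
    timing_symmetry = list((d$dd_early_correct - d$dd_late_correct) -
                             abs(d$dd_early_wrong - d$dd_late_wrong), NA)
  )
  purrr::imap_dfr(contrasts, function(cc, name) {
    v <- cc[[1]]
    dir <- cc[[2]]
    tibble::tibble(
      contrast = name, estimate = mean(v),
      conf.low = unname(quantile(v, 0.025)),
      conf.high = unname(quantile(v, 0.975)),
      direction = if (is.na(dir)) NA_character_ else dir,
      er = if (is.na(dir)) NA_real_ else evidence_ratio(v, dir))
  })
}

#' Binary probit regression of accuracy
#'
#' Probit model of trial correctness on social-information validity (or
#' presence), stimulus difficulty, stimulus color, and z-scored trial
#' number, with a subject random intercept. The accuracy trial filter
#' (drop filler and 50% judgments) is applied internally.
#'
#' @param data Judgment tibble.
#' @param predictor `"validity"` (absent/correct/wrong; absent is the
#'   reference) or `"presence"`.
#' @param config A [sampler_config()].
#' @param seed Integer seed.
#' @return A `probit_fit` with `draws`, `diagnostics`, `converged`, and
#'   metadata.
#' @export
fit_binary_probit <- function(data, predictor = c("validity", "presence"),
                              config = sampler_config(), seed = 1) {
  predictor <- match.arg(predictor)
  data <- apply_trial_filters(data, "accuracy")
  assert_columns(data, c("subject_id", "correct", "si_validity",
                         "difficulty", "col", "trial_index"))
  if (length(unique(data$correct)) < 2) {
    stop("accuracy has a single class; the probit model is not identifiable")
  }
  subjects <- sort(unique(data$subject_id))
  tz <- as.numeric(scale(data$trial_index))
  X <- if (predictor == "validity") {
    cbind(intercept = 1,
          si_correct = as.numeric(!is.na(data$si_validity) &
                                    data$si_validity == 1),
          si_wrong = as.numeric(!is.na(data$si_validity) &
                                  data$si_validity == -1),
          hard = as.numeric(data$difficulty == "hard"),
          col = data$col, trial_z = tz)
  } else {
    cbind(intercept = 1,
          si_present = as.numeric(!is.na(data$si_validity)),
          hard = as.numeric(data$difficulty == "hard"),
          col = data$col, trial_z = tz)
  }
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(seed + 7919L * (ch - 1L))
    chains[[ch]] <- bp_mcmc_cpp(
      y = as.integer(data$correct), X = X,
      subj = match(data$subject_id, subjects) - 1L,
      n_subj = length(subjects),
      iter = config$iter, warmup = config$warmup, thin = config$thin,
      prior_beta_sd = config$prior_loc_sd,
      prior_ranef_sd = config$prior_scale_sd, save_loglik = FALSE)
  }
  per_chain <- nrow(chains[[1]]$beta)
  draws <- purrr::imap_dfr(chains, function(cc, ch) {
    b <- cc$beta
    colnames(b) <- colnames(X)
    dplyr::bind_cols(
      tibble::tibble(.chain = ch, .iteration = seq_len(per_chain)),
      tibble::as_tibble(b),
      tibble::tibble(sd_subject = as.numeric(cc$sd_ranef)))
  })
  diagnostics <- fit_diagnostics(draws, colnames(X))
  structure(list(draws = draws, diagnostics = diagnostics,
                 converged = all(is.finite(diagnostics$rhat)) &&
                   max(diagnostics$rhat) <= 1.05,
                 predictor = predictor, subjects = subjects,
                 n_trials = nrow(data), config = config, seed = seed),
            class = "probit_fit")
}

#' @export
print.probit_fit <- function(x, ...) {
  cat(sprintf("binary probit fit (%s): %d subjects, %d trials\n",
              x$predictor, length(x$subjects), x$n_trials))
  invisible(x)
}

#' @rdname fit_binary_probit
#' @param x A `probit_fit`.
#' @param ... Unused.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  terms <- setdiff(names(x$draws), c(".chain", ".iteration"))
  purrr::map_dfr(terms, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
}

#' Posterior-predictive confidence distributions by treatment
#'
#' Predicted proportions of the 11 folded confidence categories (from 100%
#' confident and wrong, through 50%, to 100% confident and correct) for
#' each treatment, averaging over the design rows of the treatment, the
#' subjects' posterior intercepts, and a subsample of posterior draws.
#'
#' @param fit An `sdt_fit`.
#' @param design The design tibble the model was fitted to.
#' @param n_draws Number of posterior draws to average over.
#' @return A tibble `treatment`, `category` (folded: 1 = 100% wrong, 11 =
#'   100% correct), `proportion`; proportions sum to 1 per treatment.
#' @export
posterior_predictive_confidence <- function(fit, design, n_draws = 200) {
  stopifnot(inherits(fit, "sdt_fit"))
  assert_columns(design, c("s", "condition", "hard", "trial_z",
                           "subject_id", "col"), "design")
  d <- fit$draws
  take <- round(seq(1, nrow(d), length.out = min(n_draws, nrow(d))))
  cond <- design$condition
  X <- cbind(1,
             cond == "early-correct", cond == "late-correct",
             cond == "early-wrong", cond == "late-wrong",
             design$hard, design$trial_z) * design$s
  subj_idx <- match(design$subject_id, fit$subjects)
  beta <- as.matrix(d[take, sdt_term_names])
  thr <- as.matrix(d[take, paste0("t", 1:10)])
  ranef <- fit$ranef[take, , drop = FALSE]
  acc <- matrix(0, nrow(design), 11)
  for (k in seq_along(take)) {
    mu <- as.numeric(X %*% beta[k, ]) + ranef[k, subj_idx]
    cdf <- vapply(thr[k, ], function(t) pnorm(t - mu), numeric(length(mu)))
    p <- cbind(cdf[, 1], cdf[, -1, drop = FALSE] - cdf[, -10, drop = FALSE],
               1 - cdf[, 10])
    acc <- acc + p
  }
  acc <- acc / length(take)
  # fold onto the wrong..correct axis: orange-dominant trials keep the
  # category order, blue-dominant trials reverse it
  folded <- lapply(design$col, function(cc) if (cc == 1) 1:11 else 11:1)
  out <- purrr::map_dfr(seq_len(nrow(design)), function(i) {
    tibble::tibble(treatment = design$treatment[i],
                   category = 1:11,
                   p = acc[i, folded[[i]]])
  })
  out |>
    dplyr::group_by(.data$treatment, .data$category) |>
    dplyr::summarise(proportion = mean(.data$p), .groups = "drop")
}
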