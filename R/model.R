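#' Accumulator parameters for a single decision maker
#'
#' The model assumes evidence at judgment time is normally distributed with
#' mean `tau*col + delta_p*DT + (delta_s*ST + gamma)*lambda` on the
#' correct-option axis and variance `sigma*DT` with the diffusion scale
#' `sigma` fixed at 1. The ten confidence criteria are mirror-symmetric
#' about zero (`c_k = -c_{11-k}`) and strictly ordered.
#'
#' @param delta_easy,delta_hard Personal drift (evidence units/s) by
#'   stimulus difficulty.
#' @param delta_s Social drift per second from social-information onset.
#' @param gamma Instantaneous social shift.
#' @param tau Color bias (+ orange / - blue).
#' @param criteria The ten ordered, symmetric criteria (see
#'   [make_criteria()]).
#' @return An `accumulator_parameters` object.
#' @export
accumulator_parameters <- function(delta_easy = 0.90, delta_hard = 0.45,
                                   delta_s = 0.18, gamma = 2.41, tau = 0,
                                   criteria = make_criteria(rep(1.75, 5))) {
  if (length(criteria) != 10 || any(diff(criteria) <= 0)) {
    stop("`criteria` must be ten strictly increasing values")
  }
  if (max(abs(criteria + rev(criteria))) > 1e-8) {
    stop("`criteria` must be mirror-symmetric about zero")
  }
  structure(list(delta_easy = delta_easy, delta_hard = delta_hard,
                 delta_s = delta_s, gamma = gamma, tau = tau, sigma = 1,
                 criteria = criteria), class = "accumulator_parameters")
}

#' Evidence moments for each trial
#'
#' Closed-form mean and variance of the latent evidence at judgment time.
#' The mean is returned on both axes: `mean_correct` follows the model
#' equation `tau*col + delta_p*DT + (delta_s*ST + gamma)*lambda` (positive
#' favors the correct option), and `mean_color = col * mean_correct`
#' (positive favors orange), which is the axis on which the 11 response
#' categories from "100% blue" to "100% orange" live. Social terms are
#' zeroed when social information is absent.
#'
#' @param data Tibble with columns `dt_s`, `st_s`, `col`, `si_validity`
#'   (+1/-1, `NA` when absent) and `difficulty`.
#' @param params An [accumulator_parameters()].
#' @return The input with `mean_correct`, `mean_color`, and `var` added.
#' @export
trial_moments <- function(data, params) {
  stopifnot(inherits(params, "accumulator_parameters"))
  assert_columns(data, c("dt_s", "st_s", "col", "si_validity", "difficulty"))
  if (any(data$dt_s <= 0)) stop("decision time `dt_s` must be positive")
  si <- as.numeric(!is.na(data$si_validity))
  lambda <- ifelse(si == 1, data$si_validity, 0)
  st <- ifelse(si == 1, data$st_s, 0)
  dp <- ifelse(data$difficulty == "easy", params$delta_easy,
               params$delta_hard)
  mc <- params$tau * data$col + dp * data$dt_s +
    (params$delta_s * st + params$gamma) * lambda * si
  dplyr::mutate(data,
                mean_correct = mc,
                mean_color = .data$col * mc,
                var = params$sigma * .data$dt_s)
}

#' Category probabilities under the ordinal evidence model
#'
#' Probability of each of the 11 confidence categories given the evidence
#' mean and variance: `p_j = Phi((c_j - E)/sqrt(var)) -
#' Phi((c_{j-1} - E)/sqrt(var))` with `c_0 = -Inf` and `c_11 = Inf`.
#'
#' @param mean,var Evidence mean(s) and variance(s) (recycled).
#' @param criteria Ten strictly increasing criteria.
#' @return A numeric matrix with one row per trial and columns `p1..p11`;
#'   rows sum to 1 to within 1e-12.
#' @export
category_probabilities <- function(mean, var, criteria) {
  if (length(criteria) != 10 || any(diff(criteria) <= 0)) {
    stop("`criteria` must be ten strictly increasing values")
  }
  if (any(var <= 0)) stop("`var` must be positive")
  n <- max(length(mean), length(var))
  mean <- rep_len(mean, n)
  sdv <- sqrt(rep_len(var, n))
  cdf <- vapply(criteria, function(ck) pnorm((ck - mean) / sdv),
                numeric(n))
  cdf <- matrix(cdf, nrow = n)
  p <- cbind(cdf[, 1, drop = FALSE],
             cdf[, -1, drop = FALSE] - cdf[, -10, drop = FALSE],
             1 - cdf[, 10, drop = FALSE])
  colnames(p) <- paste0("p", 1:11)
  p
}

#' Ordinal log-likelihood of observed confidence judgments
#'
#' Sums `log p_j` over trials, with the observed category evaluated on the
#' color axis. Zero probabilities at an observed category are floored at
#' 1e-300 and flagged.
#'
#' @param data Judgment tibble (accumulation filter applied) with
#'   `confidence_category` and the predictor columns used by
#'   [trial_moments()].
#' @param params An [accumulator_parameters()].
#' @return A list with `total`, `pointwise` (tibble of per-trial log
#'   probabilities), and `n_floored`.
#' @export
log_likelihood <- function(data, params) {
  assert_columns(data, "confidence_category")
  mom <- trial_moments(data, params)
  p <- category_probabilities(mom$mean_color, mom$var, params$criteria)
  pj <- p[cbind(seq_len(nrow(p)), data$confidence_category)]
  floored <- pj < 1e-300
  pj[floored] <- 1e-300
  pointwise <- tibble::tibble(loglik = log(pj), floored = floored)
  list(total = sum(pointwise$loglik), pointwise = pointwise,
       n_floored = sum(floored))
}

#' The eight shift/drift model variants
#'
#' All combinations of the three main parameters: personal drift
#' (`delta_easy`/`delta_hard`), social drift (`delta_s`), and social shift
#' (`gamma`). The color bias and the confidence criteria are part of every
#' variant.
#'
#' @return A tibble with columns `variant`, `personal_drift`,
#'   `social_drift`, `social_shift` (eight rows; `"full"` includes all
#'   three).
#' @export
model_variants <- function() {
  grid <- tidyr::expand_grid(personal_drift = c(FALSE, TRUE),
                             social_drift = c(FALSE, TRUE),
                             social_shift = c(FALSE, TRUE))
  name <- apply(grid, 1, function(r) {
    parts <- c("personal", "drift", "shift")[unlist(r)]
    if (length(parts) == 0) "null" else paste(parts, collapse = "+")
  })
  name[name == "personal+drift+shift"] <- "full"
  dplyr::bind_cols(tibble::tibble(variant = name), grid)
}
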