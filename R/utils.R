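# internal numeric helpers

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# split-Rhat (Gelman et al. 2013): each chain halved, pooled-vs-within variance
split_rhat <- function(x, chain) {
  halves <- split(x, interaction(chain, ave(seq_along(x), chain,
                                            FUN = function(i) i > mean(i))))
  halves <- halves[lengths(halves) > 1L]
  if (length(halves) < 2L) return(NA_real_)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, var, 0)
  w <- mean(vars)
  b <- n * var(means)
  if (w <= 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}

ess_of <- function(x, chain) {
  sum(vapply(split(x, chain), function(v) {
    as.numeric(coda::effectiveSize(coda::mcmc(v)))
  }, 0))
}

assert_columns <- function(data, cols, what = "dataset") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(data)
}

# the 11-point response scale: category j -> confidence in the reported color
category_confidence <- function(j) 0.5 + 0.1 * abs(j - 6)

# reported side on the color axis: +1 orange, -1 blue, 0 for the 50% category
category_side <- function(j) sign(j - 6)
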