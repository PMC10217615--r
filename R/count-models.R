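# Count tables and probability models.
#
# A count table is a tidy data frame with columns `label` (character) and
# `count` (non-negative integers); a probability model is a data frame with
# columns `label` and `p`. Category ORDER is part of the data model: the
# discrete Fisher information depends on which categories are adjacent, so
# rows are never sorted and all operations preserve row order.

#' Build a count table
#'
#' @param counts Non-negative integer vector of category counts, in category
#'   order.
#' @param labels Optional character vector of category names; defaults to
#'   `"c1", "c2", ...`.
#'
#' @return A tibble with columns `label` and `count`.
#' @examples
#' count_table(c(148, 429, 278, 275, 72))
#' @export
count_table <- function(counts, labels = NULL) {
  counts <- check_counts(counts)
  labels <- labels %||% names(counts) %||% paste0("c", seq_along(counts))
  if (length(labels) != length(counts)) {
    abort("`labels` must have one entry per count.")
  }
  tibble(label = as.character(labels), count = unname(counts))
}

#' Build a probability table
#'
#' @param p Numeric vector of category probabilities (non-negative, summing
#'   to one), in category order.
#' @param labels Optional character vector of category names.
#'
#' @return A tibble with columns `label` and `p`.
#' @export
probability_table <- function(p, labels = NULL) {
  p <- check_prob(p)
  labels <- labels %||% names(p) %||% paste0("c", seq_along(p))
  if (length(labels) != length(p)) {
    abort("`labels` must have one entry per probability.")
  }
  tibble(label = as.character(labels), p = unname(p))
}

# ---- input coercion ---------------------------------------------------------

# Accepts a count table (data frame with `count`) or a bare numeric vector;
# returns a validated named numeric vector of counts.
as_counts <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if (!"count" %in% names(x)) {
      abort(sprintf("`%s` must have a `count` column.", arg))
    }
    cts <- check_counts(x$count, arg = arg)
    names(cts) <- if ("label" %in% names(x)) as.character(x$label) else
      paste0("c", seq_along(cts))
    return(cts)
  }
  cts <- check_counts(x, arg = arg)
  names(cts) <- names(x) %||% paste0("c", seq_along(cts))
  cts
}

# Accepts a probability table (data frame with `p`), a count table (converted
# to MLE proportions), or a numeric vector (probabilities if it sums to ~1,
# otherwise counts); returns a validated named probability vector.
as_prob <- function(x, arg = "x") {
  if (is.data.frame(x)) {
    if ("p" %in% names(x)) {
      pv <- check_prob(x$p, arg = arg)
      names(pv) <- if ("label" %in% names(x)) as.character(x$label) else
        paste0("c", seq_along(pv))
      return(pv)
    }
    if ("count" %in% names(x)) {
      cts <- as_counts(x, arg = arg)
      return(setNames(cts / sum(cts), names(cts)))
    }
    abort(sprintf("`%s` must have a `p` or `count` column.", arg))
  }
  if (!is.numeric(x)) abort(sprintf("`%s` must be numeric.", arg))
  if (abs(sum(x) - 1) <= 1e-8) {
    pv <- check_prob(x, arg = arg)
    names(pv) <- names(x) %||% paste0("c", seq_along(pv))
    return(pv)
  }
  cts <- as_counts(x, arg = arg)
  setNames(cts / sum(cts), names(cts))
}

check_counts <- function(counts, arg = "counts") {
  if (!is.numeric(counts)) abort(sprintf("`%s` must be numeric.", arg))
  if (length(counts) < 2) {
    abort(sprintf("`%s` needs at least 2 categories.", arg))
  }
  if (anyNA(counts)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(counts < 0)) abort(sprintf("`%s` contains negative counts.", arg))
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort(sprintf("`%s` contains non-integer counts.", arg))
  }
  if (sum(counts) < 1) {
    abort(sprintf("`%s` is all zero; at least one observation is required.", arg))
  }
  round(counts)
}

check_prob <- function(p, arg = "p") {
  if (!is.numeric(p)) abort(sprintf("`%s` must be numeric.", arg))
  if (length(p) < 2) abort(sprintf("`%s` needs at least 2 categories.", arg))
  if (anyNA(p)) abort(sprintf("`%s` contains missing values.", arg))
  if (any(p < 0)) abort(sprintf("`%s` contains negative probabilities.", arg))
  if (abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("`%s` must sum to 1 (got %.12g).", arg, sum(p)))
  }
  as.numeric(p)
}

# ---- MLE proportions --------------------------------------------------------

#' Maximum-likelihood category proportions
#'
#' Converts a count table into its vector of observed proportions
#' \eqn{\hat p_\ell = N_\ell / n}, the maximum-likelihood estimator of the
#' multinomial probabilities. Zero counts give zero proportions.
#'
#' @param counts A count table (data frame with a `count` column) or a
#'   numeric vector of counts.
#'
#' @return A tibble with columns `label`, `count`, and `p`.
#' @examples
#' mle_proportions(c(5, 0, 5))
#' @export
mle_proportions <- function(counts) {
  cts <- as_counts(counts, "counts")
  tibble(label = names(cts), count = unname(cts), p = unname(cts) / sum(cts))
}

# ---- synthetic probability models -------------------------------------------

#' Linear probability model
#'
#' Category probabilities increasing linearly,
#' \eqn{p_\ell = 2\ell/(k(k+1))} for \eqn{\ell = 1, \dots, k}.
#'
#' @param k Number of categories (at least 2).
#'
#' @return A probability tibble with columns `label` and `p`.
#' @examples
#' model_linear(6)
#' @export
model_linear <- function(k) {
  check_k(k, min = 2)
  probability_table(2 * seq_len(k) / (k * (k + 1)))
}

#' One-almost-zero probability model
#'
#' Near-uniform model with one vanishing cell: \eqn{p_\ell = 1/k} for
#' \eqn{\ell \le k - 2}, \eqn{p_{k-1} = \epsilon_0}, and
#' \eqn{p_k = 2/k - \epsilon_0}. The default \eqn{\epsilon_0} is the double
#' machine epsilon, making the next-to-last cell positive but never observed
#' at realistic sample sizes.
#'
#' @param k Number of categories (at least 3).
#' @param eps0 The near-zero probability, in `(0, 2/k)`.
#'
#' @return A probability tibble with columns `label` and `p`.
#' @examples
#' model_one_almost_zero(6)
#' @export
model_one_almost_zero <- function(k, eps0 = 2.220446e-16) {
  check_k(k, min = 3)
  if (!is.numeric(eps0) || length(eps0) != 1 || eps0 <= 0 || eps0 >= 2 / k) {
    abort(sprintf("`eps0` must lie strictly between 0 and 2/k = %.6g.", 2 / k))
  }
  p <- rep(1 / k, k)
  p[k - 1] <- eps0
  p[k] <- 2 / k - eps0
  probability_table(p)
}

#' Half-and-half probability model
#'
#' The first half of the categories gets probability \eqn{(1+\epsilon)/k} and
#' the second half \eqn{(1-\epsilon)/k}. Requires an even number of
#' categories; `eps = 0` is the uniform distribution.
#'
#' @param k Even number of categories (at least 2).
#' @param eps Imbalance fraction in `[0, 1)`.
#'
#' @return A probability tibble with columns `label` and `p`.
#' @examples
#' model_half_and_half(6, 0.3)
#' @export
model_half_and_half <- function(k, eps) {
  check_k(k, min = 2)
  if (k %% 2 != 0) {
    abort("`k` must be even for the half-and-half model.")
  }
  if (!is.numeric(eps) || length(eps) != 1 || eps < 0 || eps >= 1) {
    abort("`eps` must lie in [0, 1).")
  }
  probability_table(c(rep((1 + eps) / k, k / 2), rep((1 - eps) / k, k / 2)))
}

check_k <- function(k, min) {
  if (!is.numeric(k) || length(k) != 1 || k < min || k != round(k)) {
    abort(sprintf("`k` must be a single integer >= %d.", min))
  }
  invisible(as.integer(k))
}

# ---- multinomial sampling ---------------------------------------------------

#' Draw a multinomial count sample
#'
#' Exact multinomial sampling (via [stats::rmultinom()], sequential binomial
#' conditionals) of `n` trials from a probability model. An exact sampler
#' matters here: tail cells with \eqn{n p_\ell \ll 1}, as in the
#' one-almost-zero model, must receive occasional or zero counts with the
#' correct probabilities, which a normal approximation would not give.
#'
#' @param p A probability table (data frame with a `p` column) or a
#'   probability vector.
#' @param n Number of trials (at least 1).
#' @param seed Integer seed; the draw is reproducible and does not disturb
#'   the caller's random-number state.
#'
#' @return A count tibble with columns `label` and `count` summing to `n`.
#' @examples
#' sample_counts(model_linear(6), n = 600, seed = 1)
#' @export
sample_counts <- function(p, n, seed) {
  pv <- as_prob(p, "p")
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    abort("`n` must be a single integer >= 1.")
  }
  check_seed(seed)
  cts <- withr::with_seed(seed, rmultinom(1, size = n, prob = pv))[, 1]
  count_table(cts, labels = names(pv))
}

check_seed <- function(seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 ||
      !is.finite(seed) || seed != round(seed)) {
    abort("`seed` must be supplied as a single integer.")
  }
  invisible(as.integer(seed))
}

# Matrix of `reps` multinomial draws (k x reps), used by the sweeps.
sample_counts_matrix <- function(pv, n, reps, seed) {
  withr::with_seed(seed, rmultinom(reps, size = n, prob = pv))
}

# ---- category collapsing ----------------------------------------------------

#' Collapse adjacent categories of a count table
#'
#' Merges contiguous blocks of categories by summing their counts, e.g.
#' pooling a five-level Likert item into agree / neutral / disagree. Blocks
#' must form an ordered partition of the categories into contiguous runs:
#' collapsing non-adjacent categories would scramble the adjacency structure
#' that the Fisher information measure depends on.
#'
#' @param counts A count table or numeric vector of counts.
#' @param groups A list of integer vectors, each a contiguous block of
#'   category indices; together they must cover `1:k` in order.
#' @param labels Optional character vector of labels for the collapsed
#'   categories; defaults to joining the original labels with `"+"`.
#'
#' @return A count tibble with one row per block; the total count is
#'   preserved.
#' @examples
#' collapse_categories(c(148, 429, 278, 275, 72),
#'                     groups = list(1:2, 3, 4:5))
#' @export
collapse_categories <- function(counts, groups, labels = NULL) {
  cts <- as_counts(counts, "counts")
  k <- length(cts)
  if (!is.list(groups) || length(groups) < 1) {
    abort("`groups` must be a list of index blocks.")
  }
  idx <- unlist(groups, use.names = FALSE)
  if (!identical(as.integer(idx), seq_len(k))) {
    abort(paste0(
      "`groups` must partition 1:", k,
      " into contiguous, order-preserving blocks."
    ))
  }
  merged <- map_dbl(groups, function(g) sum(cts[g]))
  labels <- labels %||%
    vapply(groups, function(g) paste(names(cts)[g], collapse = "+"), "")
  count_table(merged, labels = labels)
}
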