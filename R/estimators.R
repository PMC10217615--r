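# Plug-in entropy functionals.
#
# All four functionals use the natural logarithm internally; raw entropies
# are in nats. The normalized variants divide by the maximum over the
# k-simplex and are invariant to the logarithm base. Element-wise
# conventions 0*log(0) = 0 and 0^q = 0 (q > 0) apply before summation.

#' Shannon entropy
#'
#' \eqn{H_S(p) = -\sum_\ell p_\ell \log p_\ell}, in nats, with the
#' convention \eqn{0 \log 0 = 0}. The normalized variant divides by
#' \eqn{\log k} and lies in \eqn{[0, 1]}.
#'
#' @param p A probability table (data frame with a `p` column), a count
#'   table (converted to MLE proportions), or a numeric vector.
#' @param normalized Logical; divide by the maximum `log k`?
#'
#' @return A single numeric value.
#' @examples
#' shannon_entropy(c(148, 429, 278, 275, 72), normalized = TRUE)
#' @export
shannon_entropy <- function(p, normalized = FALSE) {
  pv <- as_prob(p)
  h <- -sum(xlogx(pv))
  if (normalized) h / log(length(pv)) else h
}

#' Tsallis entropy of order q
#'
#' \eqn{H_T^q(p) = \sum_\ell (p_\ell - p_\ell^q)/(q - 1)}, \eqn{q \ne 1}.
#' The normalized variant multiplies by \eqn{(q-1)/(1 - k^{1-q})}. The
#' \eqn{q \to 1} limit is the Shannon entropy.
#'
#' @inheritParams shannon_entropy
#' @param q Entropy order, any real number other than 1.
#'
#' @return A single numeric value.
#' @examples
#' tsallis_entropy(c(148, 429, 278, 275, 72), q = 1/2, normalized = TRUE)
#' @export
tsallis_entropy <- function(p, q, normalized = FALSE) {
  if (missing(q) || !is.numeric(q) || length(q) != 1 || q == 1) {
    abort("`q` must be a single number different from 1.")
  }
  pv <- as_prob(p)
  h <- sum(pv - xpowq(pv, q)) / (q - 1)
  if (normalized) h * (q - 1) / (1 - length(pv)^(1 - q)) else h
}

#' Renyi entropy of order q
#'
#' \eqn{H_R^q(p) = \log(\sum_\ell p_\ell^q)/(1 - q)}, \eqn{q > 0},
#' \eqn{q \ne 1}. The normalized variant divides by \eqn{\log k}. The
#' \eqn{q \to 1} limit is the Shannon entropy.
#'
#' @inheritParams tsallis_entropy
#' @param q Entropy order, positive and different from 1.
#'
#' @return A single numeric value.
#' @examples
#' renyi_entropy(c(148, 429, 278, 275, 72), q = 1/3, normalized = TRUE)
#' @export
renyi_entropy <- function(p, q, normalized = FALSE) {
  if (missing(q) || !is.numeric(q) || length(q) != 1 || q <= 0 || q == 1) {
    abort("`q` must be a single positive number different from 1.")
  }
  pv <- as_prob(p)
  h <- log(sum(xpowq(pv, q))) / (1 - q)
  if (normalized) h / log(length(pv)) else h
}

#' Discrete Fisher information measure
#'
#' \eqn{H_F(p) = F_0 \sum_{\ell=1}^{k-1} (\sqrt{p_{\ell+1}} -
#' \sqrt{p_\ell})^2}, a finite-difference analogue of the Fisher information
#' of a density. It is sensitive to the ordering of the categories (unlike
#' the Shannon, Tsallis, and Renyi entropies) and vanishes at the uniform
#' distribution. With the conventional renormalization `f0 = 4` it is
#' usually, but not always, below 1; no clamping is applied.
#'
#' @inheritParams shannon_entropy
#' @param f0 Renormalization coefficient (default 4).
#'
#' @return A single numeric value.
#' @examples
#' fisher_information(c(148, 429, 278, 275, 72))
#' @export
fisher_information <- function(p, f0 = 4) {
  pv <- as_prob(p)
  f0 * sum(diff(sqrt(pv))^2)
}

#' Plug-in entropy under a spec
#'
#' Evaluates the entropy functional described by an [entropy_spec()] at a
#' probability or count table.
#'
#' @inheritParams shannon_entropy
#' @param spec An [entropy_spec()].
#'
#' @return A single numeric value.
#' @examples
#' plugin_entropy(c(148, 429, 278, 275, 72), entropy_spec("renyi", q = 2/3))
#' @export
plugin_entropy <- function(p, spec) {
  check_spec(spec)
  switch(spec$family,
    shannon = shannon_entropy(p, normalized = spec$normalized),
    tsallis = tsallis_entropy(p, q = spec$q, normalized = spec$normalized),
    renyi   = renyi_entropy(p, q = spec$q, normalized = spec$normalized),
    fisher  = fisher_information(p, f0 = spec$f0)
  )
}

check_spec <- function(spec) {
  if (!inherits(spec, "entropy_spec")) {
    abort("`spec` must be created with `entropy_spec()`.")
  }
  invisible(spec)
}

# x * log(x) with 0 * log(0) = 0
xlogx <- function(x) ifelse(x > 0, x * log(x), 0)

# x^q with 0^q = 0 for any q (incl. q < 1 where R would give Inf at 0)
xpowq <- function(x, q) ifelse(x > 0, x^q, 0)

# Column-wise entropies of a k x R matrix of proportions (sweep fast path).
entropy_cols <- function(P, spec) {
  switch(spec$family,
    shannon = -colSums(ifelse(P > 0, P * log(P), 0)),
    tsallis = colSums(P - ifelse(P > 0, P^spec$q, 0)) / (spec$q - 1),
    renyi   = log(colSums(ifelse(P > 0, P^spec$q, 0))) / (1 - spec$q),
    fisher  = spec$f0 * colSums(diff(sqrt(P))^2)
  )
}
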