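# Delta-method asymptotics for plug-in entropies under the multinomial law.
#
# sqrt(n) (p_hat - p) converges to N(0, Sigma_p) with Sigma_p = D_p - p p'.
# Propagating through the per-category component functions of each entropy
# gives the limit law of the plug-in estimate: normal for Shannon, Tsallis
# and the Fisher information measure; for the Renyi entropy the power sum
# S = sum(p_hat^q) is asymptotically normal (mu_star, sigma_star) and the
# entropy log(S)/(1-q) follows the induced "log-power-normal" law.

#' Covariance matrix of multinomial proportions
#'
#' The asymptotic covariance \eqn{\Sigma_p = D_p - p p^\top} of
#' \eqn{\sqrt{n}(\hat p - p)}: diagonal \eqn{p_\ell(1 - p_\ell)},
#' off-diagonal \eqn{-p_\ell p_j}. Rows sum to zero (proportions sum to
#' one), so the matrix is singular positive semidefinite.
#'
#' @inheritParams shannon_entropy
#'
#' @return A `k x k` symmetric matrix with category labels as dimnames.
#' @examples
#' multinomial_covariance(c(0.5, 0.5))
#' @export
multinomial_covariance <- function(p) {
  pv <- as_prob(p)
  sigma <- diag(pv) - tcrossprod(pv)
  dimnames(sigma) <- list(names(pv), names(pv))
  sigma
}

#' Gradient matrix of an entropy's component functions
#'
#' The matrix `B` of partial derivatives of the per-category component
#' functions whose sum (up to sign and constants) is the entropy:
#' for Shannon \eqn{h_\ell = p_\ell \log p_\ell} (diagonal entries
#' \eqn{\log p_\ell + 1}), for Tsallis \eqn{h_\ell = p_\ell - p_\ell^q}
#' (diagonal \eqn{1 - q p_\ell^{q-1}}), for Renyi \eqn{h_\ell = p_\ell^q}
#' (diagonal \eqn{q p_\ell^{q-1}}), and for the Fisher information
#' \eqn{h_\ell = (\sqrt{p_{\ell+1}} - \sqrt{p_\ell})^2} whose row `l` has
#' the two non-zero entries
#' \eqn{-(\sqrt{p_{\ell+1}}-\sqrt{p_\ell})/\sqrt{p_\ell}} and
#' \eqn{(\sqrt{p_{\ell+1}}-\sqrt{p_\ell})/\sqrt{p_{\ell+1}}}.
#'
#' Categories with probability below `spec$zero_floor` get zero rows and
#' columns (with a warning) for the families whose derivative diverges at
#' zero; with the floor disabled such categories raise an error.
#'
#' @inheritParams plugin_entropy
#'
#' @return A `k' x k` matrix, where `k' = k` except for the Fisher
#'   information where `k' = k - 1`.
#' @examples
#' entropy_gradient(model_linear(4), entropy_spec("shannon"))
#' @export
entropy_gradient <- function(p, spec) {
  pv <- as_prob(p)
  check_spec(spec)
  k <- length(pv)
  keep <- variance_weights(pv, spec, context = "gradient")
  if (spec$family == "fisher") {
    s <- sqrt(pv)
    B <- matrix(0, k - 1, k)
    for (l in seq_len(k - 1)) {
      if (keep[l])     B[l, l]     <- -(s[l + 1] - s[l]) / s[l]
      if (keep[l + 1]) B[l, l + 1] <-  (s[l + 1] - s[l]) / s[l + 1]
    }
    colnames(B) <- names(pv)
    return(B)
  }
  d <- switch(spec$family,
    shannon = ifelse(keep, log(pv) + 1, 0),
    tsallis = ifelse(keep, 1 - spec$q * pv^(spec$q - 1), 0),
    renyi   = ifelse(keep, spec$q * pv^(spec$q - 1), 0)
  )
  B <- diag(d, nrow = k)
  dimnames(B) <- list(names(pv), names(pv))
  B
}

# Indicator of categories that participate in variance/gradient terms.
# Exact zeros never participate (a category that cannot occur contributes
# exactly zero sampling fluctuation); positive probabilities below the
# floor are dropped with a classed warning. In the gradient context, exact
# zeros with a diverging derivative and the floor disabled are an error.
variance_weights <- function(pv, spec, context = c("variance", "gradient")) {
  context <- match.arg(context)
  keep <- pv > 0
  tiny <- keep & pv < spec$zero_floor
  if (any(tiny)) {
    warn(
      sprintf(
        "%d categor%s with p < zero_floor (%g) excluded from variance terms.",
        sum(tiny), if (sum(tiny) == 1) "y" else "ies", spec$zero_floor
      ),
      class = "entrotest_zero_floor"
    )
    keep[tiny] <- FALSE
  }
  derivative_diverges <- switch(spec$family,
    shannon = TRUE,                  # log p + 1 -> -Inf
    tsallis = spec$q < 1,            # p^(q-1) -> Inf
    renyi   = spec$q < 1,
    fisher  = TRUE                   # 1/sqrt(p) terms
  )
  if (context == "gradient" && derivative_diverges &&
      spec$zero_floor <= 0 && any(pv == 0)) {
    abort(paste0(
      "Degenerate support: zero probabilities with a diverging ",
      spec$family, " derivative and `zero_floor` disabled."
    ))
  }
  keep
}

#' Delta-method covariance of the component functions
#'
#' \eqn{\Sigma_\Delta = B \Sigma_p B^\top} with `B` from
#' [entropy_gradient()] and \eqn{\Sigma_p} from
#' [multinomial_covariance()]: the covariance of the multivariate normal
#' limit of the component functions evaluated at \eqn{\hat p}. For the
#' Shannon, Tsallis, and Renyi families `B` is diagonal and the entries have
#' simple closed forms; for the Fisher information the matrix is
#' tridiagonal-plus-rank-structure and genuinely non-diagonal.
#'
#' @inheritParams plugin_entropy
#'
#' @return A `k' x k'` symmetric positive semidefinite matrix.
#' @export
delta_covariance <- function(p, spec) {
  pv <- as_prob(p)
  B <- entropy_gradient(pv, spec)
  sigma <- multinomial_covariance(pv)
  B %*% sigma %*% t(B)
}

# ---- asymptotic laws --------------------------------------------------------

#' Asymptotic law of a plug-in entropy estimate
#'
#' Closed-form limit distribution of the plug-in entropy of a multinomial
#' sample of size `n` from probabilities `p`. Shannon, Tsallis, and the
#' Fisher information measure are asymptotically normal with mean equal to
#' the plug-in functional at `p` and an order-`1/n` delta-method variance.
#' The Renyi entropy is not asymptotically normal: the power sum
#' \eqn{S = \sum \hat p_\ell^q} is normal with mean \eqn{\mu_* = \sum
#' p_\ell^q} and variance \eqn{\sigma_*^2 = (q^2/n)(\sum p_\ell^{2q-1} -
#' (\sum p_\ell^q)^2)}, and the entropy \eqn{\log(S)/(1-q)} follows the
#' induced log-power-normal law ([renyi_limit_density()]).
#'
#' When `x` is a count table the law is evaluated at the MLE proportions
#' with `n` taken from the table total (the "sample asymptotic" law used by
#' [entropy_test()]); when `x` is a probability model, `n` must be given.
#'
#' @param x A count table (data frame with a `count` column; `n` inferred)
#'   or a probability table / vector (requires `n`).
#' @param spec An [entropy_spec()]. Normalized specs rescale mean and
#'   variance by the appropriate normalization constant (and its square).
#' @param n Sample size, required when `x` holds probabilities.
#'
#' @return An object of class `entropy_law`: a list with fields `family`,
#'   `q`, `normalized`, `shape` (`"normal"` or `"log_power_normal"`),
#'   `mean`, `variance`, `mu_star`, `sigma_star` (Renyi only), `k`, `n`,
#'   and `degenerate`. Supports [tidy()], [autoplot()], [law_density()],
#'   [law_cdf()], and [sample_law()].
#' @examples
#' gss <- count_table(c(148, 429, 278, 275, 72))
#' asymptotic_law(gss, entropy_spec("shannon"))
#' @export
asymptotic_law <- function(x, spec, n = NULL) {
  check_spec(spec)
  is_counts <- (is.data.frame(x) && "count" %in% names(x) && !"p" %in% names(x)) ||
    (!is.data.frame(x) && is.numeric(x) && abs(sum(x) - 1) > 1e-8)
  if (is_counts) {
    cts <- as_counts(x)
    n <- n %||% sum(cts)
    pv <- setNames(cts / sum(cts), names(cts))
  } else {
    pv <- as_prob(x)
    if (is.null(n)) {
      abort("`n` must be supplied when `x` holds probabilities.")
    }
  }
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    abort("`n` must be a single value >= 1.")
  }
  k <- length(pv)

  if (spec$family == "renyi") {
    law <- renyi_law(pv, n, spec, k)
  } else {
    raw_mean <- switch(spec$family,
      shannon = -sum(xlogx(pv)),
      tsallis = sum(pv - xpowq(pv, spec$q)) / (spec$q - 1),
      fisher  = spec$f0 * sum(diff(sqrt(pv))^2)
    )
    raw_var <- switch(spec$family,
      shannon = shannon_variance(pv, n, spec),
      tsallis = tsallis_variance(pv, n, spec),
      fisher  = fisher_variance(pv, n, spec)
    )
    scale <- normalization_constant(spec, k)
    law <- list(
      family = spec$family, q = spec$q, normalized = spec$normalized,
      shape = "normal",
      mean = raw_mean * scale, variance = raw_var * scale^2,
      mu_star = NULL, sigma_star = NULL, k = k, n = n
    )
  }
  law$f0 <- spec$f0
  law$renyi_variance <- spec$renyi_variance
  law$fisher_variance <- spec$fisher_variance
  law$degenerate <- law$variance <= 0
  structure(law, class = "entropy_law")
}

# Multiplier applied to the raw mean (squared for the variance).
normalization_constant <- function(spec, k) {
  if (!spec$normalized) return(1)
  switch(spec$family,
    shannon = 1 / log(k),
    renyi   = 1 / log(k),
    tsallis = (spec$q - 1) / (1 - k^(1 - spec$q)),
    fisher  = 1   # carries its own renormalization f0
  )
}

# Variance contraction: for a linear combination sum(a_l h_l(p_hat)) with
# diagonal gradient a, the delta-method variance is
# (sum p a^2 - (sum p a)^2) / n. Terms for excluded categories are zero.
contract_variance <- function(pa, pa2, n) {
  (sum(pa2) - sum(pa)^2) / n
}

shannon_variance <- function(pv, n, spec) {
  keep <- variance_weights(pv, spec)
  lp <- ifelse(keep, log(pv) + 1, 0)  # a_l = log p + 1
  contract_variance(ifelse(keep, pv * lp, 0), ifelse(keep, pv * lp^2, 0), n)
}

tsallis_variance <- function(pv, n, spec) {
  q <- spec$q
  keep <- variance_weights(pv, spec)
  # p a   = (p - q p^q) / (q - 1)
  # p a^2 = (p - 2 q p^q + q^2 p^(2q-1)) / (q - 1)^2
  pa <- ifelse(keep, (pv - q * pv^q) / (q - 1), 0)
  pa2 <- ifelse(keep, (pv - 2 * q * pv^q + q^2 * pv^(2 * q - 1)) / (q - 1)^2, 0)
  contract_variance(pa, pa2, n)
}

# Power-sum variance sigma_star^2 for the Renyi family.
renyi_power_sum_variance <- function(pv, n, spec) {
  q <- spec$q
  keep <- variance_weights(pv, spec)
  pa <- ifelse(keep, q * pv^q, 0)                 # p * q p^(q-1)
  pa2 <- ifelse(keep, q^2 * pv^(2 * q - 1), 0)    # p * (q p^(q-1))^2
  contract_variance(pa, pa2, n)
}

renyi_law <- function(pv, n, spec, k) {
  q <- spec$q
  mu_star <- sum(xpowq(pv, q))
  sigma_star2 <- renyi_power_sum_variance(pv, n, spec)
  raw_mean <- log(mu_star) / (1 - q)
  scale <- normalization_constant(spec, k)
  variance <- switch(spec$renyi_variance,
    power_sum = sigma_star2,
    delta = sigma_star2 / ((1 - q)^2 * mu_star^2) * scale^2
  )
  list(
    family = "renyi", q = q, normalized = spec$normalized,
    shape = "log_power_normal",
    mean = raw_mean * scale, variance = variance,
    mu_star = mu_star, sigma_star = sqrt(sigma_star2), k = k, n = n
  )
}

# Fisher information variance. "delta" contracts the scalar gradient of the
# functional against Sigma_p (the mode supported by Monte-Carlo
# calibration); "paper" evaluates the published closed form at scale
# f0 * Sigma_star / n, whose (k-1, k-1) diagonal term is
# (sqrt(p_k) - sqrt(p_{k-1}))^2 (1 - p_{k-1}).
fisher_variance <- function(pv, n, spec) {
  keep <- variance_weights(pv, spec)
  k <- length(pv)
  g <- fisher_scalar_gradient(pv, keep, spec$f0)
  if (spec$fisher_variance == "delta") {
    return(contract_variance(pv * g, pv * g^2, n))
  }
  # paper mode: quadratic form of the component-function covariance at
  # scale f0 / n, with the published (k-1, k-1) entry.
  B <- entropy_gradient(pv, spec)
  sigma_df <- B %*% multinomial_covariance(pv) %*% t(B)
  s <- sqrt(pv)
  sigma_df[k - 1, k - 1] <- (s[k] - s[k - 1])^2 * (1 - pv[k - 1])
  a <- rep(1, k - 1)
  spec$f0 * c(t(a) %*% sigma_df %*% a) / n
}

# d H_F / d p_j, with excluded categories' components set to zero.
fisher_scalar_gradient <- function(pv, keep, f0) {
  k <- length(pv)
  s <- sqrt(pv)
  g <- numeric(k)
  for (j in seq_len(k)) {
    if (!keep[j]) next
    acc <- 0
    if (j <= k - 1) acc <- acc - (s[j + 1] - s[j]) / s[j]
    if (j >= 2)     acc <- acc + (s[j] - s[j - 1]) / s[j]
    g[j] <- f0 * acc
  }
  g
}

#' @export
print.entropy_law <- function(x, ...) {
  lbl <- spec_label(list(family = x$family, q = x$q))
  cat(sprintf(
    "<entropy_law> %s%s: %s\n  mean %.6g, variance %.7g  (k = %d, n = %g)\n",
    lbl, if (x$normalized) " (normalized)" else "",
    x$shape, x$mean, x$variance, x$k, x$n
  ))
  if (x$shape == "log_power_normal") {
    cat(sprintf("  power sum: mu* = %.6g, sigma* = %.6g\n",
                x$mu_star, x$sigma_star))
  }
  if (x$degenerate) cat("  [degenerate: zero variance]\n")
  invisible(x)
}
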