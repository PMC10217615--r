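#' Specify an entropy functional
#'
#' Bundles the choice of entropy family, order, and the conventions used
#' when the corresponding asymptotic variance is evaluated.
#'
#' @param family One of `"shannon"`, `"tsallis"`, `"renyi"`, `"fisher"`.
#' @param q Order of the Tsallis or Renyi entropy. Must differ from 1
#'   (Tsallis) and be positive and differ from 1 (Renyi); ignored otherwise.
#' @param normalized Logical; if `TRUE` (default) the entropy is rescaled by
#'   its maximum over the k-simplex (`log k` for Shannon/Renyi,
#'   `(1 - k^(1-q))/(q - 1)` for Tsallis), so values of samples with
#'   different numbers of categories are comparable. The Fisher information
#'   measure carries its own renormalization coefficient and is not rescaled.
#' @param f0 Renormalization coefficient of the Fisher information measure
#'   (default 4).
#' @param fisher_variance `"delta"` (default) evaluates the Fisher
#'   information's asymptotic variance by the delta method,
#'   \eqn{g^\top (D_p - p p^\top) g / n} with `g` the gradient of the
#'   functional (so the renormalization enters squared); `"paper"` uses the
#'   alternative published closed form at scale \eqn{F_0 \Sigma^*/n}. Only
#'   the delta form is supported by Monte-Carlo calibration; see the
#'   methods vignette.
#' @param renyi_variance Convention for the `variance` field of a Renyi
#'   asymptotic law: `"power_sum"` (default) stores the variance
#'   \eqn{\sigma_*^2} of the power sum \eqn{S = \sum \hat p_\ell^q}, the
#'   quantity whose normal limit induces the Renyi law; `"delta"` stores the
#'   first-order variance of the entropy itself,
#'   \eqn{\sigma_*^2 / ((1-q)^2 \mu_*^2)}.
#' @param zero_floor Probabilities strictly below this threshold (default
#'   `1e-10`) are excluded from asymptotic variance computations; set to
#'   `NULL` to disable, in which case degenerate support is an error for
#'   families whose variance terms diverge at zero. See the methods
#'   vignette for why near-zero cells must be dropped from the variance but
#'   kept in the mean.
#'
#' @return An object of class `entropy_spec`.
#' @examples
#' entropy_spec("shannon")
#' entropy_spec("renyi", q = 1/3)
#' @export
entropy_spec <- function(family = c("shannon", "tsallis", "renyi", "fisher"),
                         q = NULL,
                         normalized = TRUE,
                         f0 = 4,
                         fisher_variance = c("delta", "paper"),
                         renyi_variance = c("power_sum", "delta"),
                         zero_floor = 1e-10) {
  family <- match.arg(family)
  fisher_variance <- match.arg(fisher_variance)
  renyi_variance <- match.arg(renyi_variance)
  if (family %in% c("tsallis", "renyi")) {
    if (is.null(q) || !is.numeric(q) || length(q) != 1 || !is.finite(q)) {
      abort(sprintf("`q` must be a single finite number for the %s entropy.", family))
    }
    if (q == 1) {
      abort(sprintf("`q` = 1 is not a valid %s order (the q -> 1 limit is the Shannon entropy).", family))
    }
    if (family == "renyi" && q <= 0) {
      abort("The Renyi order `q` must be positive.")
    }
  } else {
    q <- NULL
  }
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0) {
    abort("`f0` must be a single positive number.")
  }
  if (!is.null(zero_floor) &&
      (!is.numeric(zero_floor) || length(zero_floor) != 1 || zero_floor < 0)) {
    abort("`zero_floor` must be NULL or a single non-negative number.")
  }
  structure(
    list(
      family = family, q = q, normalized = isTRUE(normalized), f0 = f0,
      fisher_variance = fisher_variance, renyi_variance = renyi_variance,
      zero_floor = if (is.null(zero_floor)) 0 else zero_floor
    ),
    class = "entropy_spec"
  )
}

#' @export
print.entropy_spec <- function(x, ...) {
  cat("<entropy_spec> ", spec_label(x),
      if (x$normalized) " (normalized)" else " (raw)", "\n", sep = "")
  invisible(x)
}

# Short display label, e.g. "HS", "HT1/2", "HR2/3", "HF".
spec_label <- function(spec) {
  switch(spec$family,
    shannon = "HS",
    fisher = "HF",
    tsallis = paste0("HT", format_q(spec$q)),
    renyi = paste0("HR", format_q(spec$q))
  )
}

format_q <- function(q) {
  for (den in 2:6) {
    num <- q * den
    if (abs(num - round(num)) < 1e-9) return(paste0(round(num), "/", den))
  }
  format(q, digits = 4)
}
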