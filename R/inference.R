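# Two-sample entropy comparison and the chi-squared homogeneity baseline.

#' Two-sample asymptotic entropy test
#'
#' Tests the null hypothesis that two multinomial samples have equal
#' (population) entropy by comparing plug-in estimates through their
#' asymptotic laws:
#' \deqn{z = \frac{|H_1(\hat p_1) - H_2(\hat p_2)|}
#'   {\sqrt{\hat\sigma^2(n_1, \hat p_1) + \hat\sigma^2(n_2, \hat p_2)}},
#'   \qquad p \approx 2(1 - \Phi(z)),}
#' where each variance is the asymptotic variance evaluated at that
#' sample's own MLE proportions and sample size (not pooled). Because
#' normalized entropies live on a common `[0, 1]` scale, the two samples
#' may have different numbers of categories; with different specs the test
#' compares two different functionals (a warning notes the reinterpreted
#' null). For the Renyi family the default `"power_sum"` variance
#' convention is used.
#'
#' @param counts1,counts2 Count tables (data frames with a `count` column)
#'   or numeric count vectors.
#' @param spec1 An [entropy_spec()] for the first sample.
#' @param spec2 Spec for the second sample; defaults to `spec1`.
#'
#' @return An object of class `entropy_test` with fields `z_statistic`,
#'   `p_value`, `estimate1`, `estimate2`, `variance1`, `variance2`,
#'   `spec1`, `spec2`, `n1`, `n2`, `k1`, `k2`, and the two fitted laws.
#'   Supports [tidy()] and [glance()].
#' @examples
#' y1998 <- count_table(c(148, 429, 278, 275, 72))
#' y2018 <- count_table(c(186, 496, 229, 181, 38))
#' entropy_test(y1998, y2018, entropy_spec("shannon"))
#' @export
entropy_test <- function(counts1, counts2, spec1, spec2 = spec1) {
  check_spec(spec1)
  check_spec(spec2)
  if (!identical(spec1[c("family", "q", "normalized")],
                 spec2[c("family", "q", "normalized")])) {
    warn(paste(
      "The two samples use different entropy functionals;",
      "the null hypothesis is equality of the two different quantities."
    ), class = "entrotest_cross_type")
  }
  law1 <- asymptotic_law(as_count_tbl(counts1), spec1)
  law2 <- asymptotic_law(as_count_tbl(counts2), spec2)
  v1 <- law1$variance
  v2 <- law2$variance
  if (v1 + v2 <= 0) {
    abort("Degenerate test: both asymptotic variances are zero.")
  }
  z <- abs(law1$mean - law2$mean) / sqrt(v1 + v2)
  structure(
    list(
      z_statistic = z, p_value = 2 * (1 - pnorm(z)),
      estimate1 = law1$mean, estimate2 = law2$mean,
      variance1 = v1, variance2 = v2,
      spec1 = spec1, spec2 = spec2,
      n1 = law1$n, n2 = law2$n, k1 = law1$k, k2 = law2$k,
      law1 = law1, law2 = law2
    ),
    class = "entropy_test"
  )
}

as_count_tbl <- function(x) {
  if (is.data.frame(x)) x else count_table(x)
}

#' @export
print.entropy_test <- function(x, ...) {
  cat("Two-sample asymptotic entropy test\n")
  cat(sprintf(
    "  %s (k = %d, n = %g): %.4f   vs   %s (k = %d, n = %g): %.4f\n",
    spec_label(x$spec1), x$k1, x$n1, x$estimate1,
    spec_label(x$spec2), x$k2, x$n2, x$estimate2
  ))
  cat(sprintf("  z = %.4f,  p-value = %s\n", x$z_statistic,
              format_pval(x$p_value)))
  invisible(x)
}

# scientific notation below 1e-4 so small p-values are never printed as 0
format_pval <- function(p) {
  if (p < 1e-4) sprintf("%.4e", p) else sprintf("%.4f", p)
}

#' Tidy a two-sample entropy test
#'
#' @param x An `entropy_test`.
#' @param ... Unused.
#'
#' @return A one-row tibble with the statistic, p-value, the two estimates
#'   and variances, and the sample dimensions.
#' @export
tidy.entropy_test <- function(x, ...) {
  tibble(
    family1 = x$spec1$family, q1 = x$spec1$q %||% NA_real_,
    family2 = x$spec2$family, q2 = x$spec2$q %||% NA_real_,
    estimate1 = x$estimate1, estimate2 = x$estimate2,
    variance1 = x$variance1, variance2 = x$variance2,
    n1 = x$n1, n2 = x$n2, k1 = x$k1, k2 = x$k2,
    z_statistic = x$z_statistic, p_value = x$p_value
  )
}

#' @rdname tidy.entropy_test
#' @export
glance.entropy_test <- function(x, ...) {
  tibble(z_statistic = x$z_statistic, p_value = x$p_value)
}

#' Chi-squared homogeneity test for two count tables
#'
#' Pearson chi-squared test (no continuity correction) of the null that two
#' multinomial samples over the same `k` categories share the same
#' probability vector, on the pooled `2 x k` table with `k - 1` degrees of
#' freedom. The count-by-count baseline against which the scalar entropy
#' comparison of [entropy_test()] can be judged.
#'
#' @inheritParams entropy_test
#'
#' @return A one-row tibble with `statistic`, `df`, and `p_value`.
#' @examples
#' chisq_homogeneity(c(285, 602, 210, 196, 30), c(186, 496, 229, 181, 38))
#' @export
chisq_homogeneity <- function(counts1, counts2) {
  c1 <- as_counts(counts1, "counts1")
  c2 <- as_counts(counts2, "counts2")
  if (length(c1) != length(c2)) {
    abort("Both samples must have the same number of categories.")
  }
  if (any(c1 + c2 == 0)) {
    abort("All pooled category totals must be positive.")
  }
  ht <- suppressWarnings(chisq.test(rbind(c1, c2), correct = FALSE))
  tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = unname(ht$p.value)
  )
}
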