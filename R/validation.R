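# Simulation harness validating the asymptotic laws: Anderson-Darling
# normality sweeps, Kolmogorov-Smirnov goodness-of-fit sweeps, and
# Monte-Carlo variance calibration.

#' Define a simulation validation design
#'
#' A design is a grid of probability-model configurations (model, epsilon),
#' category counts `k`, sample-size multipliers (with `n = multiplier * k`),
#' and entropy specs. The default design is the full validation study:
#' linear, one-almost-zero (machine-epsilon cell), and half-and-half with
#' imbalance 0.1/0.3/0.5/0.8; `k` in {6, 24, 120, 720}; `n` in
#' {100k, 1000k, 10000k}; and six entropy functionals (Shannon,
#' Tsallis 1/2 and 3/2, Renyi 1/3 and 2/3, Fisher information) — 432 cells.
#'
#' Within one (model, k, n) configuration all entropy specs are evaluated
#' on the *same* replicate samples, so their test decisions are positively
#' correlated across specs, as in any shared-replicate design. Per-cell
#' seeds are derived deterministically from the master seed and the cell's
#' coordinates, so results do not depend on execution order.
#'
#' @param models Data frame with columns `model` (one of `"linear"`,
#'   `"oaz"`, `"hah"`) and `eps` (epsilon for `"hah"`, epsilon0 for
#'   `"oaz"`, `NA` for `"linear"`).
#' @param k_values Integer vector of category counts.
#' @param n_multipliers Numeric vector; sample sizes are `multiplier * k`.
#' @param specs List of [entropy_spec()] objects.
#' @param replicates Number of replicate samples per cell (default 300, the
#'   normality-sweep size; [gof_sweep()] overrides its own default of 50).
#' @param alpha Significance level for the sweep decision.
#' @param seed Master seed.
#'
#' @return An object of class `validation_design`.
#' @examples
#' validation_design(k_values = 6, n_multipliers = 100)
#' @export
validation_design <- function(models = default_models(),
                              k_values = c(6L, 24L, 120L, 720L),
                              n_multipliers = c(100, 1000, 10000),
                              specs = default_specs(),
                              replicates = 300,
                              alpha = 0.01,
                              seed = 1L) {
  stopifnot(is.data.frame(models), all(c("model", "eps") %in% names(models)))
  if (!all(models$model %in% c("linear", "oaz", "hah"))) {
    abort("`models$model` must be 'linear', 'oaz', or 'hah'.")
  }
  if (replicates < 2) abort("`replicates` must be at least 2.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must lie in (0, 1).")
  check_seed(seed)
  structure(
    list(
      models = as_tibble(models), k_values = as.integer(k_values),
      n_multipliers = n_multipliers, specs = specs,
      replicates = as.integer(replicates), alpha = alpha,
      seed = as.integer(seed)
    ),
    class = "validation_design"
  )
}

#' @rdname validation_design
#' @export
default_models <- function() {
  tibble(
    model = c("linear", "oaz", "hah", "hah", "hah", "hah"),
    eps = c(NA, 2.220446e-16, 0.1, 0.3, 0.5, 0.8)
  )
}

#' @rdname validation_design
#' @export
default_specs <- function() {
  list(
    entropy_spec("shannon", normalized = FALSE),
    entropy_spec("tsallis", q = 1 / 2, normalized = FALSE),
    entropy_spec("tsallis", q = 3 / 2, normalized = FALSE),
    entropy_spec("renyi", q = 1 / 3, normalized = FALSE),
    entropy_spec("renyi", q = 2 / 3, normalized = FALSE),
    entropy_spec("fisher", normalized = FALSE)
  )
}

model_probabilities <- function(model, k, eps) {
  switch(model,
    linear = model_linear(k),
    oaz = model_one_almost_zero(k, eps0 = eps),
    hah = model_half_and_half(k, eps = eps)
  )
}

# The (model, k, n) configurations of a design, with a stable per-config
# child seed: identical results regardless of execution order.
design_configs <- function(design) {
  cfg <- expand_grid(
    design$models,
    k = design$k_values,
    mult = design$n_multipliers
  )
  cfg$n <- cfg$mult * cfg$k
  cfg$config_id <- seq_len(nrow(cfg))
  cfg$child_seed <- child_seed(design$seed, cfg$config_id)
  cfg
}

child_seed <- function(master, i) {
  as.integer((as.numeric(master) + 104729 * as.numeric(i)) %% 2147483647L)
}

run_sweep <- function(design, test_fun, replicates) {
  cfg <- design_configs(design)
  rows <- pmap(cfg, function(model, eps, k, mult, n, config_id, child_seed) {
    pv <- as_prob(model_probabilities(model, k, eps))
    P <- sample_counts_matrix(pv, n, replicates, child_seed) / n
    bind_rows(lapply(design$specs, function(spec) {
      h <- entropy_cols(P, spec)
      degenerate <- sd(h) == 0 || !all(is.finite(h))
      p_value <- if (degenerate) NA_real_ else test_fun(h, pv, n, spec)
      tibble(
        family = spec$family, q = spec$q %||% NA_real_,
        model = model, eps = eps, k = k, n = n,
        p_value = p_value,
        reject = !is.na(p_value) & p_value < design$alpha,
        degenerate = degenerate
      )
    }))
  })
  out <- bind_rows(rows)
  attr(out, "alpha") <- design$alpha
  attr(out, "n_cells") <- nrow(out)
  attr(out, "n_reject") <- sum(out$reject, na.rm = TRUE)
  class(out) <- c("sweep_result", class(out))
  out
}

#' Anderson-Darling normality sweep
#'
#' For every design cell, draws `replicates` multinomial samples, computes
#' the (raw) plug-in entropy of each, and applies the Anderson-Darling
#' test of composite normality ([nortest::ad.test()]) to the replicate
#' values. Raw and normalized entropies give identical decisions since
#' normality is affine-invariant. Renyi cells are deliberately included:
#' although their limit law is not normal, it is close enough that
#' normality is rarely rejected, which is itself a finding the sweep
#' reproduces. Cells with degenerate (constant or non-finite) replicate
#' values are flagged, not failed.
#'
#' @param design A [validation_design()]; `alpha` defaults to 0.01.
#'
#' @return A `sweep_result` tibble with one row per (spec, model, k, n)
#'   cell: `family`, `q`, `model`, `eps`, `k`, `n`, `p_value`, `reject`,
#'   `degenerate`; attributes `n_cells` and `n_reject` summarize it.
#' @examples
#' d <- validation_design(k_values = 6, n_multipliers = 100,
#'                        replicates = 100, seed = 7)
#' normality_sweep(d)
#' @export
normality_sweep <- function(design) {
  stopifnot(inherits(design, "validation_design"))
  run_sweep(
    design,
    function(h, pv, n, spec) nortest::ad.test(h)$p.value,
    replicates = design$replicates
  )
}

#' Kolmogorov-Smirnov goodness-of-fit sweep
#'
#' For every design cell, draws replicates (default 50), computes the raw
#' plug-in entropies, and applies a one-sample Kolmogorov-Smirnov test
#' against the asymptotic law evaluated at the *true* generating
#' probabilities — the fully specified limit law, not a per-replicate
#' refit. Renyi cells are tested against the log-power-normal law.
#'
#' @param design A [validation_design()].
#' @param replicates Replicates per cell (default 50).
#' @param alpha Significance level (default 0.05).
#'
#' @return A `sweep_result` tibble (see [normality_sweep()]).
#' @examples
#' d <- validation_design(k_values = 6, n_multipliers = 100, seed = 7)
#' gof_sweep(d)
#' @export
gof_sweep <- function(design, replicates = 50, alpha = 0.05) {
  stopifnot(inherits(design, "validation_design"))
  design$alpha <- alpha
  run_sweep(
    design,
    function(h, pv, n, spec) {
      law <- quiet_law(pv, spec, n)
      if (law$degenerate) return(NA_real_)
      suppressWarnings(ks.test(h, function(x) law_cdf(x, law))$p.value)
    },
    replicates = replicates
  )
}

# asymptotic_law with zero-floor warnings muffled (sweeps hit the
# one-almost-zero cell on every call).
quiet_law <- function(pv, spec, n) {
  withCallingHandlers(
    asymptotic_law(pv, spec, n = n),
    entrotest_zero_floor = function(w) invokeRestart("muffleWarning")
  )
}

#' Monte-Carlo calibration of an asymptotic law
#'
#' Draws `replicates` multinomial samples of size `n` from `p`, computes
#' the plug-in entropy of each (for Renyi specs, the power sum
#' \eqn{\sum \hat p_\ell^q}, the quantity whose normal law the theory
#' states), and compares the empirical mean and variance with the
#' asymptotic law's. Ratios near 1 validate the law — in particular they
#' discriminate the Fisher information's `"delta"` variance mode from the
#' `"paper"` closed form.
#'
#' @inheritParams plugin_entropy
#' @param n Sample size per replicate.
#' @param replicates Number of replicates (at least 100).
#' @param seed Integer seed.
#'
#' @return A one-row tibble: `family`, `q`, `k`, `n`, `replicates`,
#'   `empirical_mean`, `empirical_variance`, `asymptotic_mean`,
#'   `asymptotic_variance`, `mean_ratio`, `variance_ratio`.
#' @examples
#' variance_calibration(model_linear(6), n = 600,
#'                      spec = entropy_spec("shannon", normalized = FALSE),
#'                      replicates = 500, seed = 1)
#' @export
variance_calibration <- function(p, n, spec, replicates = 10000, seed = 1L) {
  pv <- as_prob(p)
  check_spec(spec)
  if (replicates < 100) abort("`replicates` must be at least 100.")
  check_seed(seed)
  P <- sample_counts_matrix(pv, n, replicates, seed) / n
  law <- quiet_law(pv, spec, n)
  if (spec$family == "renyi") {
    stat <- colSums(ifelse(P > 0, P^spec$q, 0))
    asy_mean <- law$mu_star
    asy_var <- law$sigma_star^2
  } else {
    stat <- entropy_cols(P, spec) * normalization_constant(spec, length(pv))
    asy_mean <- law$mean
    asy_var <- law$variance
  }
  emp_mean <- mean(stat)
  emp_var <- var(stat)
  tibble(
    family = spec$family, q = spec$q %||% NA_real_,
    k = length(pv), n = n, replicates = replicates,
    empirical_mean = emp_mean, empirical_variance = emp_var,
    asymptotic_mean = asy_mean, asymptotic_variance = asy_var,
    mean_ratio = emp_mean / asy_mean,
    variance_ratio = emp_var / asy_var
  )
}

#' Plot a sweep result
#'
#' Tile map of per-cell p-values (log10 scale) with rejected cells
#' outlined.
#'
#' @param object A `sweep_result` from [normality_sweep()] or
#'   [gof_sweep()].
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.sweep_result <- function(object, ...) {
  df <- as_tibble(object)
  df$spec <- ifelse(is.na(df$q), toupper(substr(df$family, 1, 2)),
                    paste0(substr(df$family, 1, 1), round(df$q, 2)))
  df$cell <- paste0(df$model, ifelse(is.na(df$eps) | df$eps >= 1e-3,
                                     paste0(" ", df$eps), ""),
                    " k=", df$k, " n=", df$n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$spec, y = .data$cell,
                                   fill = log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = df[df$reject, ], shape = 4, size = 1.5) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log10 p")
}
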