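# Densities, CDFs, samplers, and tidiers for entropy limit laws.

#' Density of the Renyi entropy limit law
#'
#' The Renyi plug-in entropy is \eqn{H = \log(S)/(1-q)} where the power sum
#' \eqn{S = \sum \hat p_\ell^q} is asymptotically
#' \eqn{N(\mu_*, \sigma_*^2)}. By change of variables with
#' \eqn{s(x) = e^{(1-q)x}}, the limit density of \eqn{H =
#' \log|S|/(1 - q)} is
#' \deqn{f(x) = \frac{|1-q|\, s(x)}{\sigma_*}\left[\phi\!\Big(
#'   \frac{s(x)-\mu_*}{\sigma_*}\Big) + \phi\!\Big(
#'   \frac{-s(x)-\mu_*}{\sigma_*}\Big)\right],}
#' the second (negative-branch) term being numerically negligible whenever
#' \eqn{\mu_*/\sigma_*} is large, as it always is at realistic sample
#' sizes, but keeping the density an exact density integrating to one. For
#' normalized laws the entropy is divided by \eqn{\log k}, so the density
#' is \eqn{\log k \cdot f(x \log k)}.
#'
#' @param x Numeric vector of evaluation points.
#' @param law An `entropy_law` with shape `"log_power_normal"` (from
#'   [asymptotic_law()] with a Renyi spec).
#'
#' @return Numeric vector of density values.
#' @examples
#' law <- asymptotic_law(model_linear(6), entropy_spec("renyi", q = 1/3), n = 600)
#' renyi_limit_density(0.9, law)
#' @export
renyi_limit_density <- function(x, law) {
  if (!inherits(law, "entropy_law") || law$shape != "log_power_normal") {
    abort("`law` must be a Renyi (log_power_normal) entropy_law.")
  }
  scale <- if (law$normalized) log(law$k) else 1
  lpn_density(x * scale, law$q, law$mu_star, law$sigma_star) * scale
}

lpn_density <- function(x, q, mu, sigma) {
  s <- exp((1 - q) * x)
  abs(1 - q) * s / sigma * (dnorm((s - mu) / sigma) + dnorm((-s - mu) / sigma))
}

lpn_cdf <- function(x, q, mu, sigma) {
  s <- exp((1 - q) * x)
  # H <= x  <=>  |S| <= s for q < 1 (monotone increasing in |S|),
  #              |S| >= s for q > 1.
  inner <- pnorm((s - mu) / sigma) - pnorm((-s - mu) / sigma)
  if (q < 1) inner else 1 - inner
}

#' Density and distribution function of an entropy limit law
#'
#' Normal laws use [stats::dnorm()]/[stats::pnorm()]; Renyi laws use the
#' log-power-normal forms (see [renyi_limit_density()]).
#'
#' @inheritParams renyi_limit_density
#' @param law An `entropy_law` from [asymptotic_law()].
#'
#' @return Numeric vector of densities (`law_density`) or cumulative
#'   probabilities (`law_cdf`).
#' @export
law_density <- function(x, law) {
  check_law(law)
  if (law$shape == "log_power_normal") return(renyi_limit_density(x, law))
  dnorm(x, mean = law$mean, sd = sqrt(law$variance))
}

#' @rdname law_density
#' @export
law_cdf <- function(x, law) {
  check_law(law)
  if (law$shape == "log_power_normal") {
    scale <- if (law$normalized) log(law$k) else 1
    return(lpn_cdf(x * scale, law$q, law$mu_star, law$sigma_star))
  }
  pnorm(x, mean = law$mean, sd = sqrt(law$variance))
}

#' Draw from an entropy limit law
#'
#' Normal laws give Gaussian draws; Renyi laws draw the power sum
#' \eqn{S \sim N(\mu_*, \sigma_*^2)} and transform to
#' \eqn{\log|S|/(1-q)} (divided by \eqn{\log k} when normalized).
#' Degenerate (zero-variance) laws return constant draws with a warning.
#'
#' @param law An `entropy_law`.
#' @param size Number of draws.
#' @param seed Integer seed; reproducible, leaves the caller's RNG state
#'   untouched.
#'
#' @return Numeric vector of length `size`.
#' @examples
#' law <- asymptotic_law(count_table(c(148, 429, 278, 275, 72)),
#'                       entropy_spec("shannon"))
#' sample_law(law, 5, seed = 1)
#' @export
sample_law <- function(law, size, seed) {
  check_law(law)
  if (!is.numeric(size) || length(size) != 1 || size < 1) {
    abort("`size` must be a single integer >= 1.")
  }
  check_seed(seed)
  if (law$degenerate) {
    warn("Degenerate law: returning constant draws.",
         class = "entrotest_degenerate_law")
    return(rep(law$mean, size))
  }
  if (law$shape == "log_power_normal") {
    s <- withr::with_seed(seed, rnorm(size, law$mu_star, law$sigma_star))
    h <- log(abs(s)) / (1 - law$q)
    if (law$normalized) h <- h / log(law$k)
    return(h)
  }
  withr::with_seed(seed, rnorm(size, law$mean, sqrt(law$variance)))
}

check_law <- function(law) {
  if (!inherits(law, "entropy_law")) {
    abort("`law` must be created with `asymptotic_law()`.")
  }
  invisible(law)
}

# ---- broom-style methods ----------------------------------------------------

#' Tidy an entropy limit law
#'
#' @param x An `entropy_law`.
#' @param ... Unused.
#'
#' @return A one-row tibble with columns `family`, `q`, `normalized`,
#'   `shape`, `mean`, `variance`, `mu_star`, `sigma_star`, `k`, `n`.
#' @export
tidy.entropy_law <- function(x, ...) {
  tibble(
    family = x$family, q = x$q %||% NA_real_, normalized = x$normalized,
    shape = x$shape, mean = x$mean, variance = x$variance,
    mu_star = x$mu_star %||% NA_real_, sigma_star = x$sigma_star %||% NA_real_,
    k = x$k, n = x$n
  )
}

#' @rdname tidy.entropy_law
#' @export
glance.entropy_law <- function(x, ...) tidy.entropy_law(x, ...)

#' Plot an entropy limit law
#'
#' Draws the law's density over mean plus/minus 4.5 standard deviations.
#'
#' @param object An `entropy_law`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.entropy_law <- function(object, ...) {
  sd_eff <- if (object$shape == "log_power_normal") {
    scale <- if (object$normalized) log(object$k) else 1
    object$sigma_star / (abs(1 - object$q) * object$mu_star) / scale
  } else {
    sqrt(object$variance)
  }
  grid <- tibble(
    x = seq(object$mean - 4.5 * sd_eff, object$mean + 4.5 * sd_eff,
            length.out = 400)
  )
  grid$density <- law_density(grid$x, object)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$x, y = .data$density)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(
      x = "entropy", y = "density",
      title = sprintf("Asymptotic law (%s, k = %d, n = %g)",
                      spec_label(list(family = object$family, q = object$q)),
                      object$k, object$n)
    )
}
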