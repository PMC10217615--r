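# Shared fixtures: the GSS religious-intolerance counts (also shipped as
# extdata) and small oracle helpers used across tests.

gss98 <- c(148, 429, 278, 275, 72)   # n = 1202
gss08 <- c(285, 602, 210, 196, 30)   # n = 1323
gss18 <- c(186, 496, 229, 181, 38)   # n = 1130
gss98_collapsed <- c(577, 278, 347)  # agree / neutral / disagree pooling

# Independent double-sum oracle for the Shannon limit variance: the
# published form sum p(1-p)a^2 - 2 sum_{j<l} p_l p_j a_l a_j, written
# without the contraction shortcut the package uses.
oracle_shannon_variance <- function(p, n) {
  a <- log(p) + 1
  k <- length(p)
  s1 <- sum(p * (1 - p) * a^2)
  s2 <- 0
  for (j in 1:(k - 1)) for (l in (j + 1):k) s2 <- s2 + p[l] * p[j] * a[l] * a[j]
  (s1 - 2 * s2) / n
}

# Entrywise closed forms of the component-function covariances for the
# diagonal-gradient families (independent of the package's B Sigma B' path).
oracle_closed_covariance <- function(p, family, q = NULL) {
  k <- length(p)
  m <- matrix(0, k, k)
  for (l in 1:k) for (j in 1:k) {
    m[l, j] <- if (l == j) {
      switch(family,
        shannon = (p[l] - p[l]^2) * (log(p[l]) + 1)^2,
        tsallis = (p[l] - p[l]^2) * (1 - q * p[l]^(q - 1))^2,
        renyi   = q^2 * (p[l] - p[l]^2) * p[l]^(2 * (q - 1))
      )
    } else {
      switch(family,
        shannon = -p[l] * p[j] * (log(p[l]) + 1) * (log(p[j]) + 1),
        tsallis = -p[l] * p[j] * (1 - q * p[l]^(q - 1)) * (1 - q * p[j]^(q - 1)),
        renyi   = -q^2 * (p[l] * p[j])^q
      )
    }
  }
  m
}

# A handful of strictly positive probability vectors for property loops.
property_probs <- function() {
  list(
    c(0.5, 0.3, 0.2),
    gss98 / sum(gss98),
    as_prob_vec(model_linear(6)),
    as_prob_vec(model_half_and_half(6, 0.3)),
    c(0.05, 0.1, 0.15, 0.2, 0.25, 0.25)
  )
}

as_prob_vec <- function(tbl) tbl$p

# Quadrature of a law's density over its effective support (the invariant
# "integrates to 1" is checked over mean +/- 25 effective sd).
integrate_density <- function(law) {
  sd_eff <- if (law$shape == "log_power_normal") {
    scale <- if (law$normalized) log(law$k) else 1
    law$sigma_star / (abs(1 - law$q) * law$mu_star) / scale
  } else {
    sqrt(law$variance)
  }
  integrate(function(x) law_density(x, law),
            law$mean - 25 * sd_eff, law$mean + 25 * sd_eff,
            rel.tol = 1e-9)$value
}
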