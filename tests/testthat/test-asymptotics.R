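test_that("multinomial covariance has the Dp - pp' structure", {
  m <- multinomial_covariance(c(0.5, 0.5))
  expect_equal(unname(m), matrix(c(0.25, -0.25, -0.25, 0.25), 2))
  for (p in property_probs()) {
    sigma <- multinomial_covariance(p)
    expect_equal(unname(diag(sigma)), p * (1 - p), tolerance = 1e-14)
    expect_equal(unname(rowSums(sigma)), rep(0, length(p)), tolerance = 1e-14)
    expect_true(isSymmetric(unname(sigma)))
    expect_gte(min(eigen(sigma, symmetric = TRUE)$values), -1e-12)
  }
})

test_that("entropy gradients match their analytic forms", {
  p <- c(1 / exp(1), 1 - 1 / exp(1))
  B <- entropy_gradient(p, entropy_spec("shannon"))
  expect_equal(B[1, 1], 0, tolerance = 1e-14)

  Bf <- entropy_gradient(rep(0.25, 4), entropy_spec("fisher"))
  expect_equal(unname(Bf), matrix(0, 3, 4))

  p <- c(0.2, 0.3, 0.5)
  Bt <- entropy_gradient(p, entropy_spec("tsallis", q = 2))
  expect_equal(unname(diag(Bt)), 1 - 2 * p, tolerance = 1e-14)

  # Fisher rows carry exactly two non-zeros with opposite-sign structure
  Bf <- entropy_gradient(p, entropy_spec("fisher"))
  s <- sqrt(p)
  for (l in 1:2) {
    expect_equal(unname(Bf[l, l]), -(s[l + 1] - s[l]) / s[l], tolerance = 1e-14)
    expect_equal(unname(Bf[l, l + 1]), (s[l + 1] - s[l]) / s[l + 1],
                 tolerance = 1e-14)
    expect_equal(sum(Bf[l, ] != 0), 2)
  }
})

test_that("delta covariance equals the entrywise closed forms", {
  cases <- list(
    list(family = "shannon", q = NULL),
    list(family = "tsallis", q = 0.5),
    list(family = "tsallis", q = 1.5),
    list(family = "renyi", q = 1 / 3),
    list(family = "renyi", q = 2 / 3)
  )
  for (p in property_probs()) {
    for (cs in cases) {
      spec <- entropy_spec(cs$family, q = cs$q)
      got <- delta_covariance(p, spec)
      want <- oracle_closed_covariance(p, cs$family, cs$q)
      expect_lt(max(abs(unname(got) - want)), 1e-12)
    }
  }
  # symmetric two-point Shannon case has the +/- c checkerboard value
  c0 <- 0.25 * (log(0.5) + 1)^2
  got <- delta_covariance(c(0.5, 0.5), entropy_spec("shannon"))
  expect_equal(unname(got), matrix(c(c0, -c0, -c0, c0), 2), tolerance = 1e-14)
  # Fisher at uniform: all component gradients vanish
  expect_equal(unname(delta_covariance(rep(1 / 6, 6), entropy_spec("fisher"))),
               matrix(0, 5, 5))
})

test_that("asymptotic laws reproduce the published GSS means and variances", {
  g98 <- count_table(gss98)
  hs <- asymptotic_law(g98, entropy_spec("shannon"))
  expect_equal(hs$mean, 0.914, tolerance = 5e-4)
  expect_equal(hs$variance, 0.0000724, tolerance = 1e-7 / 0.0000724)

  hr <- asymptotic_law(g98, entropy_spec("renyi", q = 2 / 3))
  expect_equal(hr$variance, 0.0000317, tolerance = 1e-7 / 0.0000317)

  ht <- asymptotic_law(count_table(gss18), entropy_spec("tsallis", q = 1 / 2))
  expect_equal(ht$variance, 0.0000842, tolerance = 1e-7 / 0.0000842)

  hf <- asymptotic_law(g98, entropy_spec("fisher"))
  expect_equal(hf$mean, 0.516, tolerance = 1e-3)
})

test_that("variance contraction agrees with the published double-sum form", {
  for (p in property_probs()) {
    n <- 1000
    law <- asymptotic_law(p, entropy_spec("shannon", normalized = FALSE), n = n)
    expect_equal(law$variance, oracle_shannon_variance(p, n), tolerance = 1e-12)

    # same contraction for Tsallis and the Renyi power sum, via the
    # quadratic form a' Sigma_p a computed with explicit matrices
    sigma <- unname(multinomial_covariance(p))
    q <- 0.5
    a <- (1 - q * p^(q - 1)) / (q - 1)
    lawt <- asymptotic_law(p, entropy_spec("tsallis", q = q, normalized = FALSE), n = n)
    expect_equal(lawt$variance, c(t(a) %*% sigma %*% a) / n, tolerance = 1e-12)

    qr <- 1 / 3
    ar <- qr * p^(qr - 1)
    lawr <- asymptotic_law(p, entropy_spec("renyi", q = qr), n = n)
    expect_equal(lawr$sigma_star^2, c(t(ar) %*% sigma %*% ar) / n,
                 tolerance = 1e-12)
  }
})

test_that("law variance scales exactly as 1/n", {
  specs <- list(
    entropy_spec("shannon"),
    entropy_spec("tsallis", q = 1.5),
    entropy_spec("renyi", q = 2 / 3),
    entropy_spec("fisher")
  )
  p <- model_linear(6)
  for (spec in specs) {
    v1 <- asymptotic_law(p, spec, n = 600)$variance
    v2 <- asymptotic_law(p, spec, n = 1200)$variance
    expect_equal(v2, v1 / 2, tolerance = 1e-14)
  }
})

test_that("Monte-Carlo draws validate the delta variances (Linear, k = 6)", {
  p <- model_linear(6)
  n <- 6000
  reps <- 3000
  for (spec in list(entropy_spec("shannon"),
                    entropy_spec("tsallis", q = 0.5),
                    entropy_spec("renyi", q = 1 / 3),
                    entropy_spec("fisher", normalized = FALSE))) {
    cal <- variance_calibration(p, n, spec, replicates = reps, seed = 29)
    expect_gt(cal$variance_ratio, 0.9)
    expect_lt(cal$variance_ratio, 1.1)
    expect_equal(cal$mean_ratio, 1, tolerance = 0.05)
  }
})

test_that("the Renyi limit density is a proper density consistent with sampling", {
  law <- asymptotic_law(count_table(gss98), entropy_spec("renyi", q = 2 / 3))
  expect_equal(integrate_density(law), 1, tolerance = 1e-6)

  raw <- asymptotic_law(model_linear(6),
                        entropy_spec("renyi", q = 1 / 3, normalized = FALSE),
                        n = 600)
  expect_equal(integrate_density(raw), 1, tolerance = 1e-6)

  # transform-of-normal draws against the density-implied CDF
  draws <- sample_law(raw, 1e5, seed = 13)
  ks <- suppressWarnings(ks.test(draws, function(x) law_cdf(x, raw)))
  expect_lt(unname(ks$statistic), 0.01)
})

test_that("law CDF and density are mutually consistent", {
  law <- asymptotic_law(model_half_and_half(6, 0.3),
                        entropy_spec("renyi", q = 2 / 3), n = 2000)
  x0 <- law$mean
  num <- integrate(function(x) renyi_limit_density(x, law),
                   x0 - 25 * sqrt(law$variance) / (abs(1 - law$q) * law$mu_star),
                   x0, rel.tol = 1e-9)$value
  expect_equal(num, law_cdf(x0, law), tolerance = 1e-7)
})

test_that("Renyi law means collapse to the Shannon mean as q -> 1", {
  p <- gss98 / sum(gss98)
  hs <- asymptotic_law(p, entropy_spec("shannon"), n = 1202)$mean
  for (q in c(1 - 1e-6, 1 + 1e-6)) {
    hr <- asymptotic_law(p, entropy_spec("renyi", q = q), n = 1202)$mean
    expect_equal(hr, hs, tolerance = 1e-5)
  }
})

test_that("law sampling is reproducible and respects the normal parameters", {
  law <- asymptotic_law(count_table(gss98), entropy_spec("shannon"))
  a <- sample_law(law, 100, seed = 5)
  b <- sample_law(law, 100, seed = 5)
  expect_identical(a, b)

  big <- sample_law(law, 1e5, seed = 6)
  expect_equal(mean(big), law$mean, tolerance = 4 * sqrt(law$variance / 1e5) / law$mean)
  expect_equal(var(big), law$variance, tolerance = 0.05)
})

test_that("degenerate and near-zero supports are handled explicitly", {
  # point mass: zero-variance law, flagged, constant draws with a warning
  law <- asymptotic_law(probability_table(c(1, 0)), entropy_spec("shannon"),
                        n = 100)
  expect_true(law$degenerate)
  expect_equal(law$variance, 0)
  expect_warning(d <- sample_law(law, 5, seed = 1), "Degenerate")
  expect_equal(d, rep(law$mean, 5))

  # one-almost-zero: the machine-epsilon cell is floored out of the
  # variance with a classed warning, keeping it finite
  oaz <- model_one_almost_zero(6)
  expect_warning(
    law <- asymptotic_law(oaz, entropy_spec("renyi", q = 1 / 3, normalized = FALSE),
                          n = 600),
    class = "entrotest_zero_floor"
  )
  expect_lt(law$sigma_star^2, 1)

  # same law with the floor disabled keeps the huge diverging term
  law_off <- suppressWarnings(asymptotic_law(
    oaz, entropy_spec("renyi", q = 1 / 3, normalized = FALSE, zero_floor = NULL),
    n = 600
  ))
  expect_gt(law_off$sigma_star^2, 1)

  # gradients at exact zeros error without the floor, zero out with it
  pz <- c(0.5, 0.5, 0)
  expect_error(entropy_gradient(pz, entropy_spec("shannon", zero_floor = NULL)),
               "Degenerate support")
  B <- entropy_gradient(pz, entropy_spec("shannon"))
  expect_equal(B[3, 3], 0)
})

test_that("Fisher variance modes differ and only delta matches simulation", {
  p <- as_prob_vec(model_linear(6))
  n <- 6000
  delta <- asymptotic_law(p, entropy_spec("fisher"), n = n)$variance
  paper <- asymptotic_law(p, entropy_spec("fisher", fisher_variance = "paper"),
                          n = n)$variance
  expect_false(isTRUE(all.equal(delta, paper)))

  cal <- variance_calibration(p, n, entropy_spec("fisher", fisher_variance = "paper"),
                              replicates = 2000, seed = 31)
  # the published closed form is off by roughly the renormalization scale
  expect_gt(abs(cal$variance_ratio - 1), 0.5)
})
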