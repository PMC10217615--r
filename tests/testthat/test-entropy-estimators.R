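test_that("plug-in entropies of the 1998 GSS sample match published values", {
  expect_equal(shannon_entropy(gss98, normalized = TRUE), 0.914, tolerance = 5e-4)
  expect_equal(tsallis_entropy(gss98, q = 1 / 2, normalized = TRUE), 0.932,
               tolerance = 5e-4)
  expect_equal(tsallis_entropy(gss98, q = 3 / 2, normalized = TRUE), 0.919,
               tolerance = 5e-4)
  expect_equal(renyi_entropy(gss98, q = 1 / 3, normalized = TRUE), 0.967,
               tolerance = 5e-4)
  expect_equal(renyi_entropy(gss98, q = 2 / 3, normalized = TRUE), 0.939,
               tolerance = 5e-4)
  expect_lt(abs(fisher_information(gss98) - 0.516), 5e-4)
  expect_lt(abs(fisher_information(gss98_collapsed) - 0.192), 5e-4)
})

test_that("normalized entropies are extremal at uniform and point-mass inputs", {
  for (k in c(2, 5, 24)) {
    unif <- rep(1 / k, k)
    expect_equal(shannon_entropy(unif, normalized = TRUE), 1)
    expect_equal(tsallis_entropy(unif, q = 0.5, normalized = TRUE), 1)
    expect_equal(renyi_entropy(unif, q = 3, normalized = TRUE), 1)
    expect_equal(fisher_information(unif), 0)
  }
  point <- c(1, 0, 0)
  expect_equal(shannon_entropy(point), 0)
  expect_equal(tsallis_entropy(point, q = 2), 0)
  expect_equal(renyi_entropy(point, q = 2), 0)
  # the Fisher measure is not bounded by 1: an interior point mass exceeds it
  expect_equal(fisher_information(c(0, 1, 0)), 8)
})

test_that("normalized entropies stay in [0, 1], hitting 1 only at uniform", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:8, 1)
    p <- rexp(k)
    p <- p / sum(p)
    for (h in c(
      shannon_entropy(p, normalized = TRUE),
      tsallis_entropy(p, q = 0.5, normalized = TRUE),
      tsallis_entropy(p, q = 2.5, normalized = TRUE),
      renyi_entropy(p, q = 1 / 3, normalized = TRUE),
      renyi_entropy(p, q = 2, normalized = TRUE)
    )) {
      expect_gte(h, 0)
      expect_lte(h, 1)
      expect_lt(h, 1)  # not uniform with probability one
    }
  }
})

test_that("Tsallis and Renyi converge to Shannon as q approaches 1", {
  for (p in property_probs()) {
    hs <- shannon_entropy(p)
    for (q in c(1 - 1e-8, 1 + 1e-8)) {
      expect_equal(tsallis_entropy(p, q = q), hs, tolerance = 1e-6)
    }
    for (q in c(1 - 1e-6, 1 + 1e-6)) {
      expect_equal(tsallis_entropy(p, q = q), hs, tolerance = 1e-5)
      expect_equal(renyi_entropy(p, q = q), hs, tolerance = 1e-5)
    }
  }
})

test_that("normalized entropies are independent of the logarithm base", {
  p <- gss98 / sum(gss98)
  k <- length(p)
  # base-2 route computed directly in the test
  expect_equal(shannon_entropy(p, normalized = TRUE),
               -sum(p * log2(p)) / log2(k), tolerance = 1e-12)
  q <- 1 / 3
  expect_equal(renyi_entropy(p, q = q, normalized = TRUE),
               (log2(sum(p^q)) / (1 - q)) / log2(k), tolerance = 1e-12)
})

test_that("Shannon/Tsallis/Renyi are permutation invariant; Fisher is not", {
  p <- c(0.5, 0.3, 0.2)
  pp <- c(0.3, 0.5, 0.2)
  expect_equal(shannon_entropy(p), shannon_entropy(pp))
  expect_equal(tsallis_entropy(p, q = 0.5), tsallis_entropy(pp, q = 0.5))
  expect_equal(renyi_entropy(p, q = 2), renyi_entropy(pp, q = 2))
  expect_false(isTRUE(all.equal(fisher_information(p), fisher_information(pp))))
})

test_that("the Fisher functional is homogeneous of degree one (Euler identity)", {
  spec <- entropy_spec("fisher")
  for (p in property_probs()) {
    B <- entropy_gradient(p, spec)
    grad <- spec$f0 * colSums(B)  # d H_F / d p_j
    expect_equal(sum(p * grad), fisher_information(p, f0 = spec$f0),
                 tolerance = 1e-12)
  }
})

test_that("entropy orders are validated", {
  expect_error(tsallis_entropy(c(.5, .5), q = 1), "different from 1")
  expect_error(renyi_entropy(c(.5, .5), q = 0), "positive")
  expect_error(renyi_entropy(c(.5, .5), q = -1), "positive")
  expect_error(entropy_spec("tsallis"), "`q`")
  expect_error(entropy_spec("renyi", q = 1), "q")
})
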