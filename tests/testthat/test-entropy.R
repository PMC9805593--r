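test_that("equal-width binning matches an explicit histogram recount", {
  b <- bin_series(c(0, 1, 2, 3), bins = 2)
  expect_equal(b$counts, c(2, 2))
  expect_equal(b$n, 4)
  expect_equal(b$K, 2L)

  # constant input: all mass in the first cell, declared support kept
  b <- bin_series(c(5, 5, 5), bins = 4)
  expect_equal(b$counts, c(3, 0, 0, 0))
  expect_equal(b$K, 4L)

  set.seed(42)
  v <- runif(100)
  b <- bin_series(v, bins = 5)
  expect_equal(sum(b$counts), 100)
  expect_equal(b$counts, brute_histogram(v, 5))

  # the maximum lands in the top (right-closed) cell
  expect_equal(bin_series(c(0, 1), bins = 3)$counts, c(1, 0, 1))

  expect_error(bin_series(numeric(), 5), "non-empty")
  expect_error(bin_series(c(1, NA), 5), "finite")
  expect_error(bin_series(c(1, Inf), 5), "finite")
  expect_error(bin_series(1:10, 1), "bins")
})

test_that("ML probabilities are the plug-in multinomial estimates", {
  expect_equal(ml_probabilities(binned_counts(c(2, 2, 0, 0))),
               c(0.5, 0.5, 0, 0))
  expect_equal(ml_probabilities(binned_counts(c(3, 1))), c(0.75, 0.25))
  p <- ml_probabilities(binned_counts(c(5, 5, 5, 5)))
  expect_equal(-sum(p * log(p)), log(4))
  expect_error(binned_counts(c(0, 0)), "at least one")
})

test_that("shrinkage intensity follows the risk-minimizing closed form", {
  expect_equal(shrinkage_lambda(binned_counts(c(2, 2, 0, 0))), 2 / 3)
  # sum(theta^2) = 1 forces zero shrinkage
  expect_equal(shrinkage_lambda(binned_counts(c(4, 0, 0, 0))), 0)
  # estimate already at target: full shrink is a no-op
  expect_equal(shrinkage_lambda(binned_counts(c(1, 1, 1, 1))), 1)
  # single observation: target is the only usable estimate
  expect_equal(shrinkage_lambda(binned_counts(c(1, 0))), 1)
  expect_error(shrinkage_lambda(binned_counts(c(2, 2)), target = c(1, 1)),
               "probability")
  expect_error(shrinkage_lambda(binned_counts(c(2, 2)), target = c(1, 2, 3)),
               "length")
})

test_that("shrunken probabilities are the convex combination with the target", {
  js <- js_probabilities(binned_counts(c(2, 2, 0, 0)))
  expect_equal(js$theta, c(1 / 3, 1 / 3, 1 / 6, 1 / 6))
  expect_equal(js$shrinkage$lambda_hat, 2 / 3)
  expect_equal(js$shrinkage$prior_a, 2)
  expect_equal(js$shrinkage$prior_mass_m, 8)

  expect_equal(js_probabilities(binned_counts(c(4, 0, 0, 0)))$theta,
               c(1, 0, 0, 0))
  expect_equal(js_probabilities(binned_counts(c(1, 1, 1, 1)))$theta,
               rep(0.25, 4))
})

test_that("shrinkage-to-pseudocount bridge satisfies its defining identity", {
  expect_equal(prior_from_lambda(2 / 3, n = 4, K = 4), 2)
  expect_equal(prior_from_lambda(0, n = 17, K = 3), 0)
  expect_equal(prior_from_lambda(0.5, n = 10, K = 5), 2)
  expect_identical(prior_from_lambda(1, n = 10, K = 5), Inf)
  expect_error(prior_from_lambda(1.5, 4, 4), "0, 1")

  # Dirichlet posterior mean with a(lambda) equals the shrunken estimate
  # termwise, for arbitrary counts
  set.seed(7)
  for (rep in 1:50) {
    K <- sample(2:10, 1)
    counts <- rmultinom(1, sample(4:100, 1),
                        prob = rexp(K))[, 1]
    b <- binned_counts(counts)
    js <- js_probabilities(b)
    a <- js$shrinkage$prior_a
    dir_mean <- if (is.infinite(a)) rep(1 / K, K)
                else (counts + a) / (b$n + K * a)
    expect_equal(dir_mean, js$theta, tolerance = 1e-12)
  }
})

test_that("Bayes entropy is the posterior-expected entropy (digamma form)", {
  expect_equal(bayes_entropy(binned_counts(c(2, 2)), a = 1), 37 / 60,
               tolerance = 1e-12)
  expect_equal(bayes_entropy(binned_counts(c(2, 2, 0, 0)), a = 2),
               1.214321789321789, tolerance = 1e-12)
  # degenerate distribution, no prior: zero entropy exactly
  expect_equal(bayes_entropy(binned_counts(c(1000, 0)), a = 0), 0)
  # full-shrinkage limit resolves to the uniform entropy
  expect_equal(bayes_entropy(binned_counts(c(3, 1)), a = Inf), log(2))
  expect_error(bayes_entropy(binned_counts(c(2, 2)), a = -1), ">= 0")
})

test_that("Bayes entropy agrees with Monte-Carlo posterior sampling", {
  set.seed(101)
  for (rep in 1:5) {
    K <- sample(2:8, 1)
    counts <- rmultinom(1, sample(5:60, 1), prob = rexp(K))[, 1]
    a <- runif(1, 0.2, 3)
    mc <- mc_bayes_entropy(counts, a, ndraw = 5e4)
    expect_lt(abs(bayes_entropy(binned_counts(counts), a) - mc$mean),
              3 * mc$se + 1e-6)
  }
})

test_that("mixed estimator chains shrinkage, bridge and Bayes entropy", {
  expect_equal(mixed_entropy(binned_counts(c(2, 2, 0, 0))),
               1.214321789321789, tolerance = 1e-12)
  expect_equal(mixed_entropy(binned_counts(c(1, 1, 1, 1))), log(4))
  expect_equal(mixed_entropy(binned_counts(c(2, 2, 0, 0)), unit = "bits"),
               1.214321789321789 / log(2), tolerance = 1e-12)

  set.seed(5)
  counts <- rmultinom(1, 10000, prob = c(0.7, 0.1, 0.1, 0.1))[, 1]
  expect_lt(abs(mixed_entropy(binned_counts(counts)) - 0.9404479886553263),
            0.01)
})

test_that("mixed entropy is consistent as the sample grows", {
  p <- c(0.4, 0.3, 0.2, 0.1)
  truth <- -sum(p * log(p))
  set.seed(33)
  err <- sapply(c(50, 500, 5000), function(n) {
    mean(replicate(100, {
      counts <- rmultinom(1, n, prob = p)[, 1]
      abs(mixed_entropy(binned_counts(counts)) - truth)
    }))
  })
  expect_true(all(diff(err) <= 0))
})

test_that("mixed entropy is invariant to permuting the cells", {
  set.seed(9)
  for (rep in 1:20) {
    counts <- rmultinom(1, 50, prob = rexp(6))[, 1]
    expect_equal(mixed_entropy(binned_counts(counts)),
                 mixed_entropy(binned_counts(sample(counts))))
  }
})

test_that("occupied-support mode and fixed priors are available", {
  b <- binned_counts(c(3, 1, 0, 0))
  expect_false(isTRUE(all.equal(mixed_entropy(b),
                                mixed_entropy(b, support = "occupied"))))
  expect_equal(mixed_entropy(b, prior = 0),
               bayes_entropy(b, 0))
  expect_equal(mixed_entropy(b, prior = 1),
               bayes_entropy(b, 1))
})
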