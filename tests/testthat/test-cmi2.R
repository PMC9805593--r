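chain_sys <- function() {
  gaussian_system(matrix(c(1, 1, 1,
                           1, 2, 2,
                           1, 2, 3), 3, byrow = TRUE),
                  labels = c("X", "Z", "Y"))
}

test_that("Gaussian CMI matches its determinant closed form", {
  sys <- gaussian_system(matrix(c(1, 0.8, 0.8, 1), 2))
  expect_equal(gaussian_cmi(sys, 1, 2), -0.5 * log(1 - 0.64),
               tolerance = 1e-10)
  sys0 <- gaussian_system(diag(2))
  expect_equal(gaussian_cmi(sys0, 1, 2), 0)
  # chain: X and Y conditionally independent given the mediator
  expect_lt(gaussian_cmi(chain_sys(), "X", "Y", "Z"), 1e-12)
})

test_that("CMI argument validation catches misuse", {
  sys <- gaussian_system(diag(3))
  expect_error(gaussian_cmi(sys, 1, 1), "distinct")
  expect_error(gaussian_cmi(sys, 1, 2, 2), "conditioning")
  expect_error(gaussian_cmi(sys, 1, 5), "range")
  expect_error(gaussian_system(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("interference conditional integrates against the X marginal", {
  # X independent of (Y, Z): intervention changes nothing
  S <- diag(3); S[2, 3] <- S[3, 2] <- 0.6
  sys <- gaussian_system(S, labels = c("X", "Y", "Z"))
  q <- interference_conditional(sys, "X", "Y", "Z")
  expect_equal(unname(q$coef), 0.6)
  expect_equal(q$var, 1 - 0.36, tolerance = 1e-12)

  # chain: regression of Y on X given Z is 0, interference = theta(y|z)
  q <- interference_conditional(chain_sys(), "X", "Y", "Z")
  expect_equal(unname(q$coef), 1, tolerance = 1e-12)  # Y on Z slope 2/2
  expect_equal(q$var, 3 - 4 / 2, tolerance = 1e-12)

  # fork with no conditioning: interference equals the Y marginal,
  # cross-checked by 1-D numerical integration of the mixture
  # W -> X (0.8), W -> Y (0.7), unit noises
  W <- matrix(c(1, 0.8, 0.7,
                0.8, 1.64, 0.56,
                0.7, 0.56, 1.49), 3, byrow = TRUE)
  sysf <- gaussian_system(W, labels = c("W", "X", "Y"))
  q <- interference_conditional(sysf, "X", "Y")
  xg <- seq(-9, 9, length.out = 2001)
  wts <- trap_weights(xg)
  sdx <- sqrt(W[2, 2])
  a <- W[2, 3] / W[2, 2]
  s2 <- W[3, 3] - W[2, 3]^2 / W[2, 2]
  mix_m <- sum(wts * dnorm(xg, 0, sdx) * (a * xg))
  mix_v <- sum(wts * dnorm(xg, 0, sdx) * (s2 + (a * xg)^2)) - mix_m^2
  expect_equal(q$intercept, mix_m, tolerance = 1e-8)
  expect_equal(q$var, mix_v, tolerance = 1e-8)
  expect_equal(q$var, W[3, 3], tolerance = 1e-8)
})

test_that("CMI2 vanishes where no direct interaction exists", {
  v <- cmi2(gaussian_system(diag(3)), 1, 2, 3)
  expect_equal(v$total, 0)
  expect_equal(v$cmi, 0)
  expect_equal(v$kl_xy, 0)
  expect_equal(v$kl_yx, 0)

  v <- cmi2(chain_sys(), "X", "Y", "Z")
  expect_lt(v$total, 1e-10)
  expect_lt(v$cmi, 1e-10)
  expect_lt(v$kl_xy, 1e-10)
  expect_lt(v$kl_yx, 1e-10)
})

test_that("CMI2 decomposition, symmetry and invariances hold", {
  set.seed(40)
  for (rep in 1:10) {
    d <- sample(2:4, 1)
    sys <- gaussian_system(rand_pd_cov(d))
    S <- if (d > 2) 3:d else integer()
    v <- cmi2(sys, 1, 2, S)
    expect_gte(v$kl_xy, 0)
    expect_gte(v$kl_yx, 0)
    expect_gte(v$total, v$cmi)
    expect_equal(v$total, v$cmi + (v$kl_xy + v$kl_yx) / 2,
                 tolerance = 1e-10)
    # symmetry in (x, y)
    expect_equal(cmi2(sys, 2, 1, S)$total, v$total, tolerance = 1e-10)
    # invariance under affine rescaling of a variable
    D <- diag(d); D[1, 1] <- -2.7
    sys2 <- gaussian_system(D %*% sys$cov %*% D)
    expect_equal(cmi2(sys2, 1, 2, S)$total, v$total, tolerance = 1e-8)
  }
})

test_that("plain mode reduces CMI2 to ordinary conditional MI", {
  set.seed(41)
  sys <- gaussian_system(rand_pd_cov(3))
  v <- cmi2(sys, 1, 2, 3, mode = "plain")
  expect_equal(v$total, gaussian_cmi(sys, 1, 2, 3))
  expect_equal(v$kl_xy, 0)
})

test_that("closed form agrees with the quadrature oracle (spot check)", {
  set.seed(46)
  sys <- gaussian_system(rand_pd_cov(3))
  expect_equal(cmi2(sys, 1, 2, 3)$total, oracle_cmi2(sys, 1, 2, 3),
               tolerance = 1e-3)
})

test_that("compiled kernel and R path agree", {
  set.seed(47)
  for (rep in 1:10) {
    d <- sample(3:5, 1)
    sys <- gaussian_system(rand_pd_cov(d))
    pool <- seq.int(3, d)
    S <- pool[sample.int(length(pool), sample(0:(d - 2), 1))]
    v <- cmi2(sys, 1, 2, S)
    k <- meomi:::cmi2_parts_cpp(sys$cov, 1L, 2L, as.integer(S), TRUE)
    expect_equal(k, c(v$total, v$cmi, v$kl_xy, v$kl_yx),
                 tolerance = 1e-12)
  }
})

test_that("data route recovers population quantities", {
  set.seed(50)
  # chain: indirect pair given the mediator is conditionally independent
  x <- rnorm(5000); z <- x + rnorm(5000); y <- z + rnorm(5000)
  expr <- cbind(A = x, B = z, C = y)
  expect_lt(cmi2_from_data(expr, "A", "C", "B")$total, 0.01)
  # direct pair, no conditioning: matches the bivariate closed form
  x <- rnorm(5000); y <- 0.8 * x + 0.6 * rnorm(5000)
  expect_lt(abs(cmi2_from_data(cbind(a = x, b = y, c = rnorm(5000)),
                               "a", "b")$total - 0.5108256237659907),
            0.05)
})

test_that("singular conditioning is repaired with a logged ridge, not a crash", {
  set.seed(51)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  expr <- cbind(a = x, b = y, dup = x)
  expect_warning(v <- cmi2_from_data(expr, "a", "b", "dup"),
                 class = "meomi_ridge_repair")
  expect_true(is.finite(v$total))
})
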