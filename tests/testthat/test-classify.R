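test_that("shrinkage covariance hits its boundary and large-sample limits", {
  set.seed(1)
  x <- scale(matrix(rnorm(50 * 5), 50, 5), scale = FALSE)
  s <- crossprod(x) / 49
  nu <- mean(diag(s))

  # forced full shrinkage: exactly the scaled identity
  full <- shrinkage_covariance(x, lambda = 1)
  expect_equal(full$sigma, diag(nu, 5))

  # trace is preserved at every shrinkage intensity
  for (lam in c(0, 0.3, 0.7, 1)) {
    expect_equal(
      sum(diag(shrinkage_covariance(x, lambda = lam)$sigma)),
      sum(diag(s)),
      tolerance = 1e-12
    )
  }

  # large-sample: tiny analytic lambda, estimate close to the truth
  a <- matrix(rnorm(25), 5)
  sig_true <- crossprod(a) + diag(5)
  big <- matrix(rnorm(10000 * 5), ncol = 5) %*% chol(sig_true)
  sh <- shrinkage_covariance(scale(big, scale = FALSE))
  expect_lt(sh$lambda, 0.05)
  expect_lt(norm(sh$sigma - sig_true, "F") / norm(sig_true, "F"), 0.05)

  expect_error(shrinkage_covariance(x[1, , drop = FALSE]), "2 observations")
})

test_that("shrinkage keeps p = 120 covariance invertible on a CV training fold", {
  set.seed(2)
  x <- matrix(rnorm(48 * 120), 48, 120) # 60-per-class data minus a test fold
  sh <- shrinkage_covariance(scale(x, scale = FALSE))
  expect_gt(sh$lambda, 0)
  kappa <- kappa(sh$sigma)
  expect_true(is.finite(kappa))
  expect_true(all(eigen(sh$sigma, symmetric = TRUE, only.values = TRUE)$values > 0))
})

test_that("FLDA weights agree with the direct linear solve", {
  set.seed(3)
  x <- matrix(rnorm(40 * 3), 40, 3)
  y <- rep(c("a", "b"), each = 20)
  x[y == "b", ] <- x[y == "b", ] + 1
  m <- fit_flda(x, y)

  mu1 <- colMeans(x[y == "a", ])
  mu2 <- colMeans(x[y == "b", ])
  xc <- rbind(sweep(x[y == "a", ], 2, mu1), sweep(x[y == "b", ], 2, mu2))
  n <- nrow(xc)
  s <- crossprod(xc) / (n - 1)
  nu <- mean(diag(s))
  sum_w <- crossprod(xc)
  sum_w2 <- crossprod(xc^2)
  var_s <- (n / (n - 1)^3) * (sum_w2 - sum_w^2 / n)
  lam <- min(max(sum(var_s) / sum((s - diag(nu, 3))^2), 0), 1)
  w_oracle <- solve((1 - lam) * s + lam * diag(nu, 3), mu1 - mu2)

  expect_equal(m$lambda_shrink, lam, tolerance = 1e-12)
  expect_equal(m$weights, as.numeric(w_oracle), tolerance = 1e-10)
  expect_equal(m$bias, sum(w_oracle * (mu1 + mu2)) / 2, tolerance = 1e-10)
})

test_that("separated clouds are classified perfectly, identical means at chance", {
  set.seed(4)
  n <- 200
  x <- rbind(
    matrix(rnorm(n * 2, mean = -3), n, 2),
    matrix(rnorm(n * 2, mean = 3), n, 2)
  )
  y <- rep(c("lo", "hi"), each = n)
  m <- fit_flda(x, y)
  expect_equal(classification_accuracy(predict(m, x), y), 1.0)

  x0 <- matrix(rnorm(2 * n * 10), 2 * n, 10)
  m0 <- fit_flda(x0, y)
  fresh <- matrix(rnorm(2000 * 10), 2000, 10)
  acc0 <- classification_accuracy(
    predict(m0, fresh),
    rep(c("lo", "hi"), each = 1000)
  )
  expect_lt(abs(acc0 - 0.5), 0.06)

  expect_error(fit_flda(x, rep("lo", 2 * n)), "2 classes")
})

test_that("prediction uses the documented sign and tie-break conventions", {
  m <- structure(
    list(
      weights = c(1, 0), bias = 0, lambda_shrink = 0.5,
      class_means = list(a = c(1, 0), b = c(-1, 0)),
      classes = c("a", "b")
    ),
    class = "flda_model"
  )
  expect_equal(predict(m, matrix(c(1, 0), 1)), "a")
  expect_equal(predict(m, matrix(c(-1, 0), 1)), "b")
  expect_equal(predict(m, matrix(c(0, 5), 1)), "a") # exact zero -> first class
  expect_equal(predict(m, matrix(c(2, 0), 1), type = "score"), 2)
  expect_error(predict(m, matrix(0, 1, 3)), "dimension")

  # class means are assigned to their own class
  expect_equal(predict(m, rbind(c(1, 0), c(-1, 0))), c("a", "b"))
})

test_that("accuracy is the exact agreement fraction", {
  expect_equal(classification_accuracy(c("a", "b"), c("a", "b")), 1)
  expect_equal(classification_accuracy(c("a", "b"), c("b", "a")), 0)
  expect_equal(
    classification_accuracy(
      c("b", rep("a", 4), "a", rep("b", 4)), # 2 of 10 flipped
      c(rep("a", 5), rep("b", 5))
    ),
    0.8
  )
  expect_error(classification_accuracy(character(0), character(0)), "empty")
  expect_error(classification_accuracy("a", c("a", "b")), "mismatch")
})

test_that("held-out accuracy grows with class separation", {
  set.seed(5)
  accs <- vapply(c(0.5, 1.5, 3), function(d) {
    n <- 100
    x <- rbind(
      matrix(rnorm(n * 20), n, 20),
      cbind(matrix(rnorm(n, mean = d), n, 1), matrix(rnorm(n * 19), n, 19))
    )
    y <- rep(c("lo", "hi"), each = n)
    tr <- c(1:70, 101:170)
    m <- fit_flda(x[tr, ], y[tr])
    classification_accuracy(predict(m, x[-tr, ]), y[-tr])
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
})

test_that("label permutation yields chance-level held-out accuracy", {
  set.seed(42)
  accs <- replicate(100, {
    n <- 200
    x <- matrix(rnorm(n * 10), n, 10)
    y <- sample(rep(c("a", "b"), n / 2))
    tr <- sample(n, 140)
    m <- fit_flda(x[tr, ], y[tr])
    classification_accuracy(predict(m, x[-tr, ]), y[-tr])
  })
  band <- 1.96 * sqrt(0.25 / (100 * 60))
  expect_lt(abs(mean(accs) - 0.5), band)
})
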