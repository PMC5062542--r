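test_that("class templates are per-class trial means", {
  dat <- array(0, c(4, 5, 2))
  dat[1, , ] <- 1
  dat[2, , ] <- 3
  dat[3, , ] <- 2
  dat[4, , ] <- -2
  ep <- toy_epochs(dat, labels = c("low", "low", "high", "high"))
  tpl <- class_templates(ep)
  expect_equal(tpl$class_ids, c("high", "low"))
  expect_true(all(tpl$P$low == 2))
  expect_true(all(tpl$P$high == 0)) # t and -t average to zero

  one <- subset_epochs(ep, trials = c(1, 3))
  tpl1 <- class_templates(one)
  expect_true(all(tpl1$P$low == 1)) # mean of one trial is the trial

  expect_error(class_templates(subset_epochs(ep, trials = 1:2)), "2 classes")
})

test_that("the dense reference equals the sparse Toeplitz construction", {
  set.seed(5)
  dat <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  labels <- c("low", "high", "low")
  ep <- toy_epochs(dat, labels = labels)
  tpl <- class_templates(ep)
  ref <- build_reference(ep, tpl)

  # brute-force Y = D1 P1 + D2 P2 with explicit binary Toeplitz onset blocks
  ns <- 4
  d_for <- function(cl) {
    d <- matrix(0, 3 * ns, ns)
    for (j in which(labels == cl)) d[(j - 1) * ns + 1:ns, ] <- diag(ns)
    d
  }
  y_oracle <- d_for("high") %*% tpl$P$high + d_for("low") %*% tpl$P$low
  expect_equal(ref$Y, y_oracle, ignore_attr = TRUE)

  # all trials of one class: Y is that template tiled
  ep1 <- subset_epochs(ep, trials = c(1, 3))
  y1 <- build_reference(ep1, tpl)$Y
  expect_equal(y1, rbind(tpl$P$low, tpl$P$low), ignore_attr = TRUE)

  # row count contract
  set.seed(6)
  big <- toy_epochs(array(rnorm(60 * 60 * 2), c(60, 60, 2)))
  expect_equal(nrow(build_reference(big, class_templates(big))$Y), 3600)

  ep_bad <- ep
  ep_bad$labels[1] <- "other"
  expect_error(build_reference(ep_bad, tpl), "outside the template classes")
})

test_that("fit_cca matches the generalized-eigenproblem oracle and cancor", {
  set.seed(8)
  for (p in c(3, 6)) {
    x <- matrix(rnorm(400 * p), 400, p)
    y <- x %*% matrix(rnorm(p * p), p) + 0.5 * matrix(rnorm(400 * p), 400, p)
    bank <- fit_cca(x, y)
    oracle <- cca_bruteforce(x, y)
    expect_equal(bank$rho, oracle$rho[seq_along(bank$rho)], tolerance = 1e-8)
    expect_equal(bank$rho, cancor(x, y)$cor, tolerance = 1e-8)
    for (k in seq_len(ncol(bank$W))) {
      expect_gt(abs_cosine(bank$W[, k], oracle$w[, k]), 1 - 1e-6)
    }
  }
})

test_that("canonical correlations behave at the self, independent and shared-signal limits", {
  set.seed(9)
  x <- matrix(rnorm(500 * 4), 500, 4)
  expect_equal(fit_cca(x, x)$rho, rep(1, 4), tolerance = 1e-8)

  y_ind <- matrix(rnorm(2000 * 4), 2000, 4)
  x_ind <- matrix(rnorm(2000 * 4), 2000, 4)
  expect_lt(max(fit_cca(x_ind, y_ind)$rho), 0.1)

  s <- rnorm(2000)
  bank <- fit_cca(cbind(s, rnorm(2000)), cbind(s, rnorm(2000)))
  expect_equal(bank$rho[1], 1, tolerance = 1e-6)
  expect_gt(abs_cosine(bank$W[, 1], c(1, 0)), 0.99)

  # scale invariance of the canonical correlations
  y <- x %*% matrix(rnorm(16), 4) + matrix(rnorm(500 * 4), 500, 4)
  expect_equal(fit_cca(7.3 * x, y)$rho, fit_cca(x, y)$rho, tolerance = 1e-10)

  xz <- x
  xz[, 2] <- 4
  colnames(xz) <- c("a", "flat", "c", "d")
  expect_error(fit_cca(xz, y), "flat")
})

test_that("filter selection keeps the top-correlation columns", {
  set.seed(10)
  x <- matrix(rnorm(300 * 4), 300, 4)
  y <- x %*% matrix(rnorm(16), 4) + matrix(rnorm(300 * 4), 300, 4)
  bank <- fit_cca(x, y)
  expect_equal(select_filters(bank, 4)$W, bank$W)
  two <- select_filters(bank, 2)
  expect_equal(two$rho, bank$rho[1:2])
  expect_equal(ncol(two$A), 2)
  expect_error(select_filters(bank, 0), ">= 1")
  expect_error(select_filters(bank, 5), "exceeds")
})

test_that("spatial patterns invert the filters", {
  expect_equal(compute_patterns(diag(3)), diag(3))

  set.seed(11)
  w <- matrix(rnorm(16), 4)
  expect_equal(compute_patterns(w), t(solve(w)), tolerance = 1e-10)

  # rectangular orthonormal filters on whitened data: A = W
  q <- qr.Q(qr(matrix(rnorm(12), 4, 3)))[, 1:2]
  expect_equal(compute_patterns(q, diag(4)), q, tolerance = 1e-10)

  # covariance formula reduces to the inverse-transpose for square W
  sig <- crossprod(matrix(rnorm(64), 8)) / 8 + diag(8)
  w8 <- matrix(rnorm(64), 8)
  expect_equal(compute_patterns(w8, sig), t(solve(w8)), tolerance = 1e-8)

  expect_error(compute_patterns(matrix(0, 2, 2)), "singular")
})

test_that("feature extraction follows the 60 x 2 virtual-electrode layout", {
  set.seed(12)
  dat <- array(rnorm(4 * 60 * 2), c(4, 60, 2))
  ep <- toy_epochs(dat)
  bank <- structure(
    list(
      W = diag(2), A = diag(2), rho = c(1, 1),
      sigma_x = diag(2), channel_labels = c("ch1", "ch2")
    ),
    class = "filter_bank"
  )
  f <- extract_features(ep, bank)
  expect_equal(dim(f$x), c(4, 120))
  expect_equal(f$x[2, 1:60], dat[2, , 1]) # identity filters: raw traces
  expect_equal(f$x[2, 61:120], dat[2, , 2])

  bank2 <- bank
  bank2$W[1, 1] <- 2 # doubling w1 doubles the first block only
  f2 <- extract_features(ep, bank2)
  expect_equal(f2$x[, 1:60], 2 * f$x[, 1:60])
  expect_equal(f2$x[, 61:120], f$x[, 61:120])

  short <- toy_epochs(array(rnorm(4 * 59 * 2), c(4, 59, 2)))
  expect_error(extract_features(short, bank), "60 samples")
})

test_that("raw-electrode features mirror the filtered layout", {
  ep <- separable_epochs(5, nch = 3, seed = 13)
  f <- extract_features_raw(ep, c("C3", "Pz"))
  expect_equal(dim(f$x), c(10, 120))
  expect_equal(f$x[1, 1:60], ep$data[1, , 1], ignore_attr = TRUE)

  dup <- extract_features_raw(ep, c("Pz", "Pz"))
  expect_equal(dup$x[, 1:60], dup$x[, 61:120])

  expect_error(extract_features_raw(ep, c("C3", "Xz")), "Xz")
})

test_that("the first virtual electrode separates the classes better than any raw channel", {
  cfg <- sim_config(seed = 0)
  ep <- decimate_epochs(baseline_correct(simulate_epochs(cfg)), 5)
  eeg <- subset_epochs(ep, channels = which(ep$channel_roles == "EEG"))
  tpl <- class_templates(eeg)
  bank <- select_filters(fit_cca(probeload:::stack_epochs(eeg), build_reference(eeg, tpl)), 2)

  sep <- function(tr, labels) {
    m1 <- colMeans(tr[labels == "low", , drop = FALSE])
    m2 <- colMeans(tr[labels == "high", , drop = FALSE])
    v <- (apply(tr[labels == "low", , drop = FALSE], 2, var) +
      apply(tr[labels == "high", , drop = FALSE], 2, var)) / 2
    sum((m1 - m2)^2) / mean(v)
  }
  virt <- extract_features(eeg, bank)$x[, 1:60]
  raw_best <- max(vapply(
    seq_len(dim(eeg$data)[3]),
    function(c) sep(eeg$data[, , c], eeg$labels), numeric(1)
  ))
  expect_gt(sep(virt, eeg$labels), raw_best * 1.5)
})
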