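make_rec <- function(data, fs = 500, roles = NULL, events = NULL) {
  nch <- ncol(data)
  continuous_recording(
    data, fs, paste0("ch", seq_len(nch)), roles %||% rep("EEG", nch),
    events = events %||% tibble::tibble(onset = integer(), label = character())
  )
}

test_that("band-pass rejects DC and 50 Hz but passes mid-band", {
  fs <- 500
  t <- seq_len(10 * fs) / fs
  trim <- (2 * fs):(8 * fs) # ignore filter edges

  dc <- make_rec(matrix(1, length(t), 1), fs)
  expect_lt(max(abs(bandpass_filter(dc)$data[trim, 1])), 1e-3)

  s10 <- make_rec(matrix(sin(2 * pi * 10 * t), ncol = 1), fs)
  amp10 <- max(abs(bandpass_filter(s10)$data[trim, 1]))
  expect_equal(amp10, 1, tolerance = 0.01)

  # zero-phase two-pass response of the 4th-order design at 50 Hz is |H|^2 = 0.124
  s50 <- make_rec(matrix(sin(2 * pi * 50 * t), ncol = 1), fs)
  amp50 <- max(abs(bandpass_filter(s50)$data[trim, 1]))
  expect_lt(amp50, 0.13)
  expect_gt(amp50, 0.05)

  expect_error(bandpass_filter(s10, 1, 300), "fs/2")
})

test_that("common average reference zeroes the EEG mean and spares EOG", {
  r <- make_rec(cbind(c(3, 1), c(1, -1)), fs = 100)
  out <- common_average_reference(r)
  expect_equal(out$data[1, ], c(ch1 = 1, ch2 = -1))
  expect_equal(out$data[2, ], c(ch1 = 1, ch2 = -1))

  set.seed(4)
  big <- make_rec(matrix(rnorm(200 * 33), 200, 33),
    roles = c(rep("EEG", 32), "EOG")
  )
  out <- common_average_reference(big)
  expect_lt(max(abs(rowMeans(out$data[, 1:32]))), 1e-10)
  expect_equal(out$data[, 33], big$data[, 33]) # EOG untouched

  single <- make_rec(matrix(rnorm(100), ncol = 1))
  expect_error(common_average_reference(single), ">= 2 EEG channels")
})

test_that("epoching uses half-open windows and preserves labels", {
  ev <- tibble::tibble(onset = c(500L, 1200L, 2000L), label = c("low", "high", "low"))
  r <- make_rec(matrix(rnorm(3000 * 2), 3000, 2), 500, events = ev)
  ep <- epoch_recording(r)
  expect_equal(dim(ep$data), c(3, 350, 2))
  expect_equal(ep$labels, ev$label)
  expect_equal(ep$times[1], -0.1)

  # epoch content is the raw slice
  expect_equal(ep$data[2, , 1], r$data[1200 + (-50:299), 1], ignore_attr = TRUE)

  bad <- make_rec(matrix(rnorm(1000), ncol = 1), 500,
    events = tibble::tibble(onset = 10L, label = "low")
  )
  expect_error(epoch_recording(bad), "too close")
})

test_that("baseline correction removes the pre-stimulus mean and trims to 0.6 s", {
  dat <- array(5, c(2, 350, 3))
  ep <- toy_epochs(dat, fs = 500, t0 = -0.1)
  out <- baseline_correct(ep)
  expect_equal(dim(out$data), c(2, 300, 3))
  expect_true(all(out$data == 0))

  # baseline mean 2, post-stimulus mean 7 -> corrected post-stimulus mean 5
  dat2 <- array(0, c(1, 350, 1))
  dat2[1, 1:50, 1] <- 2
  dat2[1, 51:350, 1] <- 7
  out2 <- baseline_correct(toy_epochs(dat2, fs = 500, t0 = -0.1))
  expect_equal(mean(out2$data), 5)

  expect_error(
    baseline_correct(toy_epochs(array(0, c(1, 300, 1)), fs = 500, t0 = 0)),
    "baseline"
  )
})

test_that("block decimation averages non-overlapping blocks and is linear", {
  x <- array(1:10, c(1, 10, 1))
  out <- decimate_epochs(toy_epochs(x, fs = 500), 5)
  expect_equal(as.vector(out$data), c(3, 8))
  expect_equal(out$fs, 100)

  const <- decimate_epochs(toy_epochs(array(2.5, c(2, 300, 2)), fs = 500), 5)
  expect_equal(dim(const$data), c(2, 60, 2))
  expect_true(all(const$data == 2.5))

  set.seed(1)
  a <- array(rnorm(2 * 300 * 2), c(2, 300, 2))
  b <- array(rnorm(2 * 300 * 2), c(2, 300, 2))
  lhs <- decimate_epochs(toy_epochs(3 * a - 2 * b, fs = 500), 5)$data
  rhs <- 3 * decimate_epochs(toy_epochs(a, fs = 500), 5)$data -
    2 * decimate_epochs(toy_epochs(b, fs = 500), 5)$data
  expect_equal(lhs, rhs, tolerance = 1e-12)

  expect_error(decimate_epochs(toy_epochs(a, fs = 500), 0), "factor")
  expect_error(decimate_epochs(toy_epochs(array(0, c(1, 299, 1)), fs = 500), 5), "divisible")
})

test_that("averaging commutes with decimation", {
  set.seed(2)
  ep <- toy_epochs(array(rnorm(6 * 300 * 2), c(6, 300, 2)), fs = 500)
  dec_then_avg <- apply(decimate_epochs(ep, 5)$data, c(2, 3), mean)
  avg <- apply(ep$data, c(2, 3), mean)
  avg_then_dec <- apply(array(avg, c(5, 60, 2)), c(2, 3), mean)
  expect_equal(dec_then_avg, avg_then_dec, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("the orchestrator applies the stages in the documented order", {
  calls <- character(0)
  wrap <- function(name, fn) {
    force(fn) # bind the original before the namespace binding is mocked
    function(...) {
      calls <<- c(calls, name)
      fn(...)
    }
  }
  local_mocked_bindings(
    bandpass_filter = wrap("filter", bandpass_filter),
    common_average_reference = wrap("car", common_average_reference),
    epoch_recording = wrap("epoch", epoch_recording),
    sobi_unmix = wrap("sobi", sobi_unmix),
    remove_eog_sources = wrap("clean", remove_eog_sources),
    baseline_correct = wrap("baseline", baseline_correct),
    decimate_epochs = wrap("decimate", decimate_epochs),
    .package = "probeload"
  )
  sim <- simulate_recording(quick_cfg(seed = 21, blink_rate = 6))
  ep <- preprocess_recording(sim$recording)
  expect_equal(calls, c("filter", "car", "epoch", "sobi", "clean", "baseline", "decimate"))
  expect_equal(dim(ep$data)[2], 60)
  expect_equal(ep$fs, 100)
})
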