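test_that("ERP templates follow the component closed form and class modulation", {
  # empty component list: identity case
  expect_equal(
    make_erp_template(default_components()[0, ], 500, n_channels = 3),
    matrix(0, 300, 3)
  )

  comp <- erp_component("P2", 0.18, 2, 0.05, topography = rep(1, 4))
  tpl <- make_erp_template(comp, 500, c(0, 0.6), "low")
  expect_equal(dim(tpl), c(300, 4))
  expect_equal(max(tpl), 2, tolerance = 1e-12)
  expect_equal((which.max(tpl[, 1]) - 1) / 500, 0.18, tolerance = 1e-9)

  # high class with a -15 ms latency shift: peak earlier, height preserved
  comp2 <- erp_component("P2", 0.18, 2, 0.05, rep(1, 4), class_lat_shift = -0.015)
  tph <- make_erp_template(comp2, 500, c(0, 0.6), "high")
  expect_lte(abs((which.max(tph[, 1]) - 1) / 500 - 0.165), 1.1 / 500)
  expect_equal(max(tph), 2, tolerance = 2e-3)

  # latency outside the window is rejected
  bad <- erp_component("P3", 0.7, 2, 0.05, rep(1, 4))
  expect_error(make_erp_template(bad, 500), "outside window")
})

test_that("probe onsets respect the inter-tone interval range", {
  set.seed(7)
  onsets <- probeload:::draw_onset_times(1001, c(6, 30))
  gaps <- diff(onsets)
  expect_length(gaps, 1000)
  expect_true(all(gaps >= 6 & gaps <= 30))
})

test_that("simulated recordings have the configured trial counts and are reproducible", {
  cfg <- quick_cfg(seed = 7)
  sim1 <- simulate_recording(cfg)
  sim2 <- simulate_recording(cfg)
  expect_identical(sim1$recording$data, sim2$recording$data)

  sim3 <- simulate_recording(quick_cfg(seed = 8))
  expect_false(identical(sim1$recording$data[1:100, 1], sim3$recording$data[1:100, 1]))

  expect_length(sim1$truth$onsets$low, 12)
  expect_length(sim1$truth$onsets$high, 12)
  expect_equal(sum(sim1$recording$events$label == "low"), 12)

  # default trial count matches the protocol's 30 stimulations per block
  expect_equal(sim_config()$n_trials_per_class, 30)
})

test_that("noiseless simulation round-trips the clean class templates", {
  cfg <- quick_cfg(
    noise = list(one_over_f_scale = 0, alpha_scale = 0, white_scale = 0),
    seed = 3
  )
  sim <- simulate_recording(cfg)
  ep <- epoch_recording(sim$recording)
  for (cl in c("low", "high")) {
    avg <- apply(ep$data[ep$labels == cl, , seq_len(32), drop = FALSE], c(2, 3), mean)
    expect_equal(avg, sim$truth$clean_epoch_means[[cl]],
      tolerance = 1e-9, ignore_attr = TRUE
    )
  }
})

test_that("reduced P1 gain lowers the high-class P1-window amplitude", {
  comps <- default_components()
  tl <- make_erp_template(comps, 500, c(0, 0.6), "low")
  th <- make_erp_template(comps, 500, c(0, 0.6), "high")
  win <- seq(round(0.04 * 500), round(0.08 * 500))
  cz <- match("Cz", default_eeg_labels())
  expect_lt(mean(th[win, cz]), mean(tl[win, cz]))
})

test_that("blink injection has the documented EOG closed form and frontal decay", {
  cfg <- quick_cfg(seed = 5)
  sim <- simulate_recording(cfg)

  # rate 0: identity
  expect_identical(inject_ocular_artifacts(sim$recording, 0), sim$recording)

  # single blink on a silent recording: vertical bipolar peak = 2 * amplitude
  labs <- c(default_eeg_labels(), unname(default_eog_labels()))
  silent <- continuous_recording(
    matrix(0, 5000, 36), 500, labs,
    c(rep("EEG", 32), rep("EOG", 4))
  )
  set.seed(1)
  out <- inject_ocular_artifacts(silent, blink_rate = 6, blink_amp = 80)
  truth <- attr(out, "artifact_truth")
  expect_length(truth$blink_onsets, 1)
  veog <- out$data[, "VEOGU"] - out$data[, "VEOGL"]
  expect_equal(max(veog), 2 * 80, tolerance = 1e-3)

  # frontal channels receive more blink than occipital ones
  topo <- truth$blink_topography
  expect_gt(topo[match("Fp1", labs)], topo[match("Oz", labs)])

  # missing EOG channels are reported by name
  noeog <- continuous_recording(
    matrix(0, 1000, 32), 500, default_eeg_labels(), rep("EEG", 32)
  )
  expect_error(inject_ocular_artifacts(noeog, 10), "VEOGU")
})

test_that("direct epoch simulation is deterministic and carries both classes", {
  cfg <- quick_cfg(seed = 9)
  e1 <- simulate_epochs(cfg)
  e2 <- simulate_epochs(cfg)
  expect_identical(e1$data, e2$data)
  expect_equal(sort(unique(e1$labels)), c("high", "low"))
  expect_equal(dim(e1$data), c(24, 350, 36))
})
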