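#' Define an auditory evoked potential component
#'
#' A component is a Gaussian bump in time (parameterized by its full width at
#' half maximum) with a fixed scalp topography, plus a class modulation: an
#' amplitude multiplier and a latency shift applied in the high-workload class.
#'
#' @param name component label (`"P1"`, `"N1"`, `"P2"`, `"N2"`, `"P3"`, ...).
#' @param peak_latency peak time in seconds after stimulus onset.
#' @param amplitude signed peak amplitude in microvolts.
#' @param width full width at half maximum, seconds (> 0).
#' @param topography numeric per-channel weight vector, max-abs 1, at least one
#'   nonzero entry.
#' @param class_amp_scale amplitude multiplier in the high-workload class.
#' @param class_lat_shift latency shift (seconds) added in the high-workload
#'   class; negative means earlier.
#' @return one-row tibble (components are stacked with `dplyr::bind_rows()`).
#' @export
erp_component <- function(name, peak_latency, amplitude, width, topography,
                          class_amp_scale = 1, class_lat_shift = 0) {
  if (width <= 0) rlang::abort("`width` must be > 0")
  topography <- as.numeric(topography)
  if (all(topography == 0)) rlang::abort("`topography` needs at least one nonzero entry")
  tibble::tibble(
    name = name, peak_latency = peak_latency, amplitude = amplitude,
    width = width, topography = list(topography),
    class_amp_scale = class_amp_scale, class_lat_shift = class_lat_shift
  )
}

#' Default component table for the synthetic auditory ERP
#'
#' Standard auditory evoked potential morphology: P1 (50 ms, +1 uV), N1
#' (100 ms, -3 uV, fronto-central), P2 (180 ms, +2.5 uV, centro-parietal), N2
#' (250 ms, -1.5 uV) and P3 (350 ms, +2 uV, parietal). The default
#' high-workload modulation mirrors the directions reported for ignored
#' auditory probes under load - reduced P1 amplitude (x0.7), earlier N1
#' (-10 ms) and earlier P2 (-15 ms) - with free-parameter magnitudes; none of
#' these values is a measured quantity.
#'
#' @param channel_labels EEG montage labels used to evaluate the topographies.
#' @return tibble of components (see [erp_component()]).
#' @export
default_components <- function(channel_labels = default_eeg_labels()) {
  dplyr::bind_rows(
    erp_component("P1", 0.050, 1.0, 0.030,
      topo_gaussian(channel_labels, 0, 0.10, 0.8),
      class_amp_scale = 0.7
    ),
    erp_component("N1", 0.100, -3.0, 0.050,
      topo_gaussian(channel_labels, 0, 0.25, 1.0),
      class_lat_shift = -0.010
    ),
    erp_component("P2", 0.180, 2.5, 0.060,
      topo_gaussian(channel_labels, 0, -0.15, 0.8),
      class_lat_shift = -0.015
    ),
    erp_component("N2", 0.250, -1.5, 0.080,
      topo_gaussian(channel_labels, 0, 0.20, 0.9)
    ),
    erp_component("P3", 0.350, 2.0, 0.120,
      topo_gaussian(channel_labels, 0, -0.55, 0.8)
    )
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic EEG/EOG generator. Defaults emulate the
#' acquisition protocol the chain targets: 32-channel 10-20 EEG plus 4 EOG
#' electrodes at 500 Hz, 30 probes per workload condition with uniform 6-30 s
#' inter-tone intervals, 1/f + alpha + sensor-noise background, and sporadic
#' blinks.
#'
#' @param channel_labels EEG labels (10-20 names present in
#'   [montage_positions()]).
#' @param eog_labels named character vector of the 4 EOG electrodes
#'   (`left`/`right` outer canthi, `above`/`below` the left eye).
#' @param fs sampling rate, Hz. Must exceed twice the 40 Hz band edge.
#' @param n_trials_per_class probes per workload condition (>= 1).
#' @param iti_range inter-tone interval range in seconds, `c(min, max)`.
#' @param components component tibble, see [default_components()].
#' @param noise list with elements `one_over_f_scale` (mean channel RMS of the
#'   spatially mixed 1/f background, uV), `alpha_scale` (10 Hz posterior
#'   rhythm RMS at its strongest channel, uV), `white_scale` (independent
#'   sensor noise SD per channel, uV).
#' @param blink_rate blink events per minute (continuous recordings only).
#' @param blink_amp blink amplitude at the vertical EOG electrodes, uV.
#' @param saccade_rate horizontal saccade events per minute (continuous
#'   recordings only; a visually demanding multitask display elicits frequent
#'   gaze shifts).
#' @param saccade_amp saccade amplitude at the outer canthi, uV.
#' @param seed integer seed; identical seeds give bit-identical recordings.
#' @return a `sim_config` list.
#' @export
sim_config <- function(channel_labels = default_eeg_labels(),
                       eog_labels = default_eog_labels(),
                       fs = 500,
                       n_trials_per_class = 30,
                       iti_range = c(6, 30),
                       components = default_components(channel_labels),
                       noise = list(one_over_f_scale = 5, alpha_scale = 2, white_scale = 1),
                       blink_rate = 10,
                       blink_amp = 100,
                       saccade_rate = 15,
                       saccade_amp = 40,
                       seed = NULL) {
  cfg <- list(
    channel_labels = channel_labels, eog_labels = eog_labels, fs = fs,
    n_trials_per_class = n_trials_per_class, iti_range = iti_range,
    components = components, noise = noise,
    blink_rate = blink_rate, blink_amp = blink_amp,
    saccade_rate = saccade_rate, saccade_amp = saccade_amp, seed = seed
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$iti_range[1] < 0 || cfg$iti_range[2] <= cfg$iti_range[1]) {
    rlang::abort("`iti_range` must satisfy 0 <= min < max")
  }
  if (cfg$n_trials_per_class < 1) rlang::abort("`n_trials_per_class` must be >= 1")
  if (cfg$fs <= 2 * 40) rlang::abort("`fs` must exceed twice the 40 Hz band edge")
  if (length(cfg$eog_labels) != 4) rlang::abort("exactly 4 EOG labels required")
  if (!all(c("left", "right", "above", "below") %in% names(cfg$eog_labels))) {
    rlang::abort("`eog_labels` must be named left/right/above/below")
  }
  invisible(cfg)
}

#' Evaluate the noise-free class template
#'
#' Sums the component Gaussians (with the high-class amplitude scale and
#' latency shift applied when `class = "high"`) over the requested window.
#'
#' @param components component tibble ([erp_component()] rows).
#' @param fs sampling rate, Hz.
#' @param window `c(start, end)` in seconds, half-open `[start, end)`.
#' @param class `"low"` or `"high"`.
#' @param n_channels channel count; required when `components` is empty,
#'   otherwise inferred from the topographies.
#' @return samples x channels matrix in microvolts. Deterministic.
#' @export
#' @examples
#' tpl <- make_erp_template(default_components(), fs = 500)
#' dim(tpl) # 300 x 32
make_erp_template <- function(components, fs, window = c(0, 0.6),
                              class = c("low", "high"), n_channels = NULL) {
  class <- match.arg(class)
  idx <- seq.int(round(window[1] * fs), round(window[2] * fs) - 1)
  t <- idx / fs
  if (nrow(components) == 0) {
    if (is.null(n_channels)) rlang::abort("`n_channels` required for an empty component list")
    return(matrix(0, length(t), n_channels))
  }
  nch <- length(components$topography[[1]])
  tpl <- matrix(0, length(t), nch)
  for (i in seq_len(nrow(components))) {
    amp <- components$amplitude[i] *
      (if (class == "high") components$class_amp_scale[i] else 1)
    lat <- components$peak_latency[i] +
      (if (class == "high") components$class_lat_shift[i] else 0)
    if (lat < window[1] || lat >= window[2]) {
      rlang::abort(sprintf(
        "component %s: latency %.3f s (class %s) outside window [%.3f, %.3f)",
        components$name[i], lat, class, window[1], window[2]
      ))
    }
    bump <- amp * exp(-4 * log(2) * (t - lat)^2 / components$width[i]^2)
    tpl <- tpl + outer(bump, components$topography[[i]])
  }
  tpl
}

# Probe onset times: first onset 2-4 s into the recording, then uniform
# inter-tone intervals; every consecutive gap lies inside iti_range.
draw_onset_times <- function(n_onsets, iti_range) {
  gaps <- stats::runif(n_onsets - 1, iti_range[1], iti_range[2])
  cumsum(c(stats::runif(1, 2, 4), gaps))
}

# FFT-shaped noise: real white noise re-weighted by gain(|f|), preserving
# conjugate symmetry. Each column is one independent realization, rescaled to
# unit SD. The transform length is padded to a fast composite size (mixed-radix
# FFTs degrade to O(n^2) on near-prime lengths) and the tail discarded.
shaped_noise <- function(n, n_series, fs, gain_fn) {
  m <- stats::nextn(n, c(2, 3, 5))
  freqs <- c(seq(0, floor(m / 2)), seq(-ceiling(m / 2) + 1, -1)) * fs / m
  g <- gain_fn(abs(freqs))
  g[1] <- 0 # no DC
  out <- matrix(0, n, n_series)
  for (j in seq_len(n_series)) {
    w <- stats::rnorm(m)
    x <- Re(stats::fft(stats::fft(w) * g, inverse = TRUE))[seq_len(n)] / m
    out[, j] <- x / stats::sd(x)
  }
  out
}

# Spatially mixed EEG background: 1/f-power sources projected through random
# smooth scalp topographies (volume conduction), posterior-weighted 10 Hz
# alpha, independent sensor noise. Returns samples x channels (uV).
background_noise <- function(n_samples, fs, channel_labels, noise) {
  nch <- length(channel_labels)
  pos <- montage_positions(channel_labels)
  out <- matrix(0, n_samples, nch)
  if (noise$one_over_f_scale > 0) {
    cx <- stats::runif(nch, -1, 1)
    cy <- stats::runif(nch, -1, 1)
    cw <- stats::runif(nch, 0.4, 0.9)
    mix <- vapply(
      seq_len(nch),
      function(s) exp(-((pos$x - cx[s])^2 + (pos$y - cy[s])^2) / (2 * cw[s]^2)),
      numeric(nch)
    ) # channels x sources
    src <- shaped_noise(n_samples, nch, fs,
      function(f) ifelse(f < 0.5, 1 / sqrt(0.5), 1 / sqrt(f))
    )
    bg <- src %*% t(mix)
    bg <- bg * (noise$one_over_f_scale / mean(apply(bg, 2, stats::sd)))
    out <- out + bg
  }
  if (noise$alpha_scale > 0) {
    n_alpha <- 3
    ax <- stats::runif(n_alpha, -0.5, 0.5)
    ay <- stats::runif(n_alpha, -1, -0.4)
    mix <- vapply(
      seq_len(n_alpha),
      function(s) exp(-((pos$x - ax[s])^2 + (pos$y - ay[s])^2) / (2 * 0.6^2)),
      numeric(nch)
    )
    src <- shaped_noise(n_samples, n_alpha, fs,
      function(f) exp(-(f - 10)^2 / (2 * 1.5^2))
    )
    al <- src %*% t(mix)
    peak <- max(apply(al, 2, stats::sd))
    if (peak > 0) al <- al * (noise$alpha_scale / peak)
    out <- out + al
  }
  if (noise$white_scale > 0) {
    out <- out + matrix(stats::rnorm(n_samples * nch, sd = noise$white_scale), n_samples, nch)
  }
  out
}

#' Simulate a continuous EEG/EOG session
#'
#' Generates a two-block session (one low-workload block, one high-workload
#' block) of background EEG with class-dependent auditory evoked responses
#' added at probe onsets drawn with uniform inter-tone intervals, and blink
#' artifacts at `blink_rate` per minute. EOG channels carry sensor noise plus
#' the artifact projections only.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (a [continuous_recording()]) and
#'   `truth`, the ground truth: per-class onset samples, component/artifact
#'   mixing topographies, and noise-free per-class epoch templates over
#'   `[-0.1, 0.6)` s (`clean_epoch_means`).
#' @export
simulate_recording <- function(config) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  n_pc <- config$n_trials_per_class
  n_onsets <- 2 * n_pc
  onset_times <- draw_onset_times(n_onsets, config$iti_range)
  labels <- rep(c("low", "high"), each = n_pc)
  n_samples <- ceiling((onset_times[n_onsets] + 1) * fs)
  onset_samples <- round(onset_times * fs) + 1L

  eeg_labels <- config$channel_labels
  all_labels <- c(eeg_labels, unname(config$eog_labels))
  roles <- c(rep("EEG", length(eeg_labels)), rep("EOG", 4))

  data <- matrix(0, n_samples, length(all_labels))
  data[, seq_along(eeg_labels)] <-
    background_noise(n_samples, fs, eeg_labels, config$noise)
  if (config$noise$white_scale > 0) {
    data[, length(eeg_labels) + 1:4] <-
      matrix(stats::rnorm(n_samples * 4, sd = config$noise$white_scale), n_samples, 4)
  }

  tpl <- list(
    low = make_erp_template(config$components, fs, c(0, 0.6), "low"),
    high = make_erp_template(config$components, fs, c(0, 0.6), "high")
  )
  tpl_len <- nrow(tpl$low)
  for (k in seq_len(n_onsets)) {
    rows <- onset_samples[k] + seq_len(tpl_len) - 1L
    data[rows, seq_along(eeg_labels)] <-
      data[rows, seq_along(eeg_labels)] + tpl[[labels[k]]]
  }

  rec <- continuous_recording(
    data, fs, all_labels, roles,
    events = tibble::tibble(onset = onset_samples, label = labels)
  )

  blink_truth <- NULL
  if (config$blink_rate > 0 || (config$saccade_rate %||% 0) > 0) {
    rec <- inject_ocular_artifacts(rec, config$blink_rate, config$blink_amp,
      saccade_rate = config$saccade_rate %||% 0,
      saccade_amp = config$saccade_amp %||% 40,
      eog_labels = config$eog_labels
    )
    blink_truth <- attr(rec, "artifact_truth")
    attr(rec, "artifact_truth") <- NULL
  }

  pre <- matrix(0, round(0.1 * fs), length(eeg_labels))
  mixing <- do.call(cbind, config$components$topography)
  colnames(mixing) <- config$components$name
  truth <- list(
    onsets = split(onset_samples, labels)[c("low", "high")],
    labels = labels,
    mixing = mixing,
    clean_epoch_means = list(low = rbind(pre, tpl$low), high = rbind(pre, tpl$high)),
    blinks = blink_truth,
    config = config
  )
  list(recording = rec, truth = truth)
}

#' Inject blink (and optional saccade) artifacts
#'
#' Adds positive blink bumps (~0.4 s raised-cosine) with a frontal-to-posterior
#' decaying scalp topography. The above-eye and below-eye EOG electrodes
#' receive the full amplitude with opposite polarity, so the vertical bipolar
#' derivation (above - below) peaks at exactly `2 * blink_amp`; the two canthi
#' receive small same-polarity weights (0.15 / 0.10). Saccades, when enabled,
#' are smoothed horizontal steps of random direction with opposite polarity at
#' the two canthi.
#'
#' @param recording a [continuous_recording()] containing the 4 EOG channels.
#' @param blink_rate blinks per minute; `0` returns the input unchanged.
#' @param blink_amp blink amplitude at the vertical EOG electrodes, uV.
#' @param seed optional seed; `NULL` continues the current RNG stream.
#' @param saccade_rate saccades per minute (default 0).
#' @param saccade_amp saccade amplitude at the canthi, uV.
#' @param eog_labels named EOG labels (see [default_eog_labels()]).
#' @return the recording with artifacts added; attribute `artifact_truth`
#'   holds the blink onset samples and full-channel blink topography.
#' @export
inject_ocular_artifacts <- function(recording, blink_rate, blink_amp = 100,
                                    seed = NULL, saccade_rate = 0,
                                    saccade_amp = 50,
                                    eog_labels = default_eog_labels()) {
  stopifnot(inherits(recording, "continuous_recording"))
  missing <- setdiff(unname(eog_labels), recording$channel_labels)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing EOG channel(s): ", paste(missing, collapse = ", ")))
  }
  if (blink_rate == 0 && saccade_rate == 0) return(recording)
  if (!is.null(seed)) set.seed(seed)

  fs <- recording$fs
  n <- nrow(recording$data)
  eeg <- eeg_idx(recording)
  pos <- montage_positions(recording$channel_labels[eeg])
  w_eeg <- exp(-sqrt(pos$x^2 + (pos$y - 1.3)^2) / 0.5)

  topo <- numeric(ncol(recording$data))
  topo[eeg] <- w_eeg
  topo[match(eog_labels[["above"]], recording$channel_labels)] <- 1
  topo[match(eog_labels[["below"]], recording$channel_labels)] <- -1
  topo[match(eog_labels[["left"]], recording$channel_labels)] <- 0.15
  topo[match(eog_labels[["right"]], recording$channel_labels)] <- 0.10

  dur <- 0.4
  blink_len <- round(dur * fs)
  bump <- sin(pi * seq_len(blink_len) / (blink_len + 1))^2

  draw_times <- function(rate_per_min) {
    if (rate_per_min <= 0) return(numeric(0))
    t <- cumsum(stats::rexp(ceiling(rate_per_min / 60 * n / fs * 3) + 10,
      rate = rate_per_min / 60
    ))
    t[t < (n / fs - dur - 0.1)]
  }

  blink_times <- draw_times(blink_rate)
  for (bt in blink_times) {
    rows <- round(bt * fs) + seq_len(blink_len)
    recording$data[rows, ] <- recording$data[rows, ] +
      blink_amp * outer(bump, topo)
  }

  if (saccade_rate > 0) {
    sac_topo <- numeric(ncol(recording$data))
    sac_topo[eeg] <- 0.2 * pos$x * exp(-(pos$y - 0.9)^2 / 0.4)
    sac_topo[match(eog_labels[["left"]], recording$channel_labels)] <- 1
    sac_topo[match(eog_labels[["right"]], recording$channel_labels)] <- -1
    sac_len <- round(0.3 * fs)
    ramp <- stats::plogis(seq(-6, 6, length.out = round(0.05 * fs)))
    sac <- c(ramp, rep(1, sac_len - 2 * length(ramp)), rev(ramp))
    for (st in draw_times(saccade_rate)) {
      rows <- round(st * fs) + seq_along(sac)
      dirn <- sample(c(-1, 1), 1)
      recording$data[rows, ] <- recording$data[rows, ] +
        dirn * saccade_amp * outer(sac, sac_topo)
    }
  }

  attr(recording, "artifact_truth") <- list(
    blink_onsets = round(blink_times * fs) + 1L,
    blink_topography = topo
  )
  recording
}

#' Simulate an epoch set directly
#'
#' Draws stimulus-locked epochs (class template plus fresh background noise per
#' trial) without synthesizing the full continuous session - statistically
#' equivalent input for the spatial-filtering and classification stages, at a
#' fraction of the cost. Blink artifacts are not injected here; use
#' [simulate_recording()] for the ocular-correction path.
#'
#' @param config a [sim_config()].
#' @param tmin,tmax epoch window in seconds, half-open `[tmin, tmax)`.
#' @return an [epoch_set()] at `config$fs` with randomized trial order and the
#'   4 EOG channels carrying sensor noise.
#' @export
simulate_epochs <- function(config, tmin = -0.1, tmax = 0.6) {
  validate_sim_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)
  fs <- config$fs
  idx <- seq.int(round(tmin * fs), round(tmax * fs) - 1)
  times <- idx / fs
  ns <- length(times)
  n_trials <- 2 * config$n_trials_per_class
  labels <- sample(rep(c("low", "high"), config$n_trials_per_class))

  eeg_labels <- config$channel_labels
  all_labels <- c(eeg_labels, unname(config$eog_labels))
  roles <- c(rep("EEG", length(eeg_labels)), rep("EOG", 4))
  nch <- length(all_labels)

  post <- times >= 0
  tpl <- list(
    low = make_erp_template(config$components, fs, c(0, tmax), "low"),
    high = make_erp_template(config$components, fs, c(0, tmax), "high")
  )

  long <- background_noise(ns * n_trials, fs, eeg_labels, config$noise)
  dat <- array(0, c(n_trials, ns, nch))
  for (j in seq_len(n_trials)) {
    ep <- long[(j - 1) * ns + seq_len(ns), , drop = FALSE]
    ep[post, ] <- ep[post, ] + tpl[[labels[j]]]
    dat[j, , seq_along(eeg_labels)] <- ep
  }
  if (config$noise$white_scale > 0) {
    dat[, , length(eeg_labels) + 1:4] <-
      stats::rnorm(n_trials * ns * 4, sd = config$noise$white_scale)
  }
  epoch_set(dat, times, fs, labels, all_labels, roles)
}
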