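#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward-backward
#' (`signal::filtfilt`), so the effective response is 8th-order with zero group
#' delay - ERP latencies are not shifted. EEG and EOG channels are filtered
#' identically.
#'
#' @param recording a [continuous_recording()].
#' @param low,high band edges in Hz; defaults 1 and 40.
#' @return the filtered recording.
#' @export
bandpass_filter <- function(recording, low = 1, high = 40) {
  stopifnot(inherits(recording, "continuous_recording"))
  nyq <- recording$fs / 2
  if (!(low > 0 && low < high && high < nyq)) {
    rlang::abort("band edges must satisfy 0 < low < high < fs/2")
  }
  bf <- signal::butter(4, c(low, high) / nyq, type = "pass")
  n <- nrow(recording$data)
  # reflect-pad so filter edge transients fall outside the retained segment
  npad <- min(n - 1, ceiling(3 * recording$fs / low))
  for (j in seq_len(ncol(recording$data))) {
    x <- recording$data[, j]
    xp <- c(
      2 * x[1] - x[seq(npad + 1, 2)],
      x,
      2 * x[n] - x[seq(n - 1, n - npad)]
    )
    recording$data[, j] <- signal::filtfilt(bf, xp)[npad + seq_len(n)]
  }
  recording
}

#' Common average reference
#'
#' Subtracts, at every sample, the instantaneous mean over EEG channels from
#' each EEG channel. EOG channels are left untouched (they are bipolar
#' derivation inputs, not scalp sites). After this step the EEG data are rank
#' deficient by one.
#'
#' @param recording a [continuous_recording()] with at least 2 EEG channels.
#' @return the re-referenced recording.
#' @export
common_average_reference <- function(recording) {
  stopifnot(inherits(recording, "continuous_recording"))
  eeg <- eeg_idx(recording)
  if (length(eeg) < 2) rlang::abort("common average reference needs >= 2 EEG channels")
  recording$data[, eeg] <- recording$data[, eeg] -
    rowMeans(recording$data[, eeg, drop = FALSE])
  recording
}

#' Extract stimulus-locked epochs
#'
#' Cuts one epoch per event over the half-open window `[tmin, tmax)` relative
#' to the event onset sample (time 0 is the onset sample itself), so a
#' `[-0.1, 0.6)` s window at 500 Hz yields exactly 350 samples.
#'
#' @param recording a [continuous_recording()] with events.
#' @param tmin,tmax window in seconds relative to onset.
#' @return an [epoch_set()] containing all channels; trial order follows event
#'   order and labels are carried over.
#' @export
epoch_recording <- function(recording, tmin = -0.1, tmax = 0.6) {
  stopifnot(inherits(recording, "continuous_recording"))
  if (nrow(recording$events) == 0) rlang::abort("recording has no events")
  fs <- recording$fs
  rel <- seq.int(round(tmin * fs), round(tmax * fs) - 1)
  first <- recording$events$onset + rel[1]
  last <- recording$events$onset + rel[length(rel)]
  bad <- which(first < 1 | last > nrow(recording$data))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "event(s) too close to the recording edge (index %s)",
      paste(bad, collapse = ", ")
    ))
  }
  n_trials <- nrow(recording$events)
  dat <- array(0, c(n_trials, length(rel), ncol(recording$data)))
  for (j in seq_len(n_trials)) {
    dat[j, , ] <- recording$data[recording$events$onset[j] + rel, ]
  }
  epoch_set(
    dat, rel / fs, fs, recording$events$label,
    recording$channel_labels, recording$channel_roles
  )
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window, then retains only the post-stimulus part of the epoch (times
#' >= 0). With the default `[-0.1, 0)` baseline on a `[-0.1, 0.6)` epoch this
#' maps 350 samples at 500 Hz to 300.
#'
#' @param epochs an [epoch_set()].
#' @param baseline `c(start, end)` in seconds, half-open, inside the epoch.
#' @return the baseline-corrected, post-stimulus [epoch_set()].
#' @export
baseline_correct <- function(epochs, baseline = c(-0.1, 0)) {
  stopifnot(inherits(epochs, "epoch_set"))
  # work on the integer sample grid to avoid floating-point window leaks
  grid <- round(epochs$times * epochs$fs)
  in_base <- grid >= round(baseline[1] * epochs$fs) & grid < round(baseline[2] * epochs$fs)
  if (!any(in_base)) rlang::abort("baseline window outside the epoch")
  keep <- grid >= 0
  base_mean <- apply(epochs$data[, in_base, , drop = FALSE], c(1, 3), mean)
  dat <- epochs$data[, keep, , drop = FALSE]
  dat <- sweep(dat, c(1, 3), base_mean, "-")
  epoch_set(
    dat, epochs$times[keep], epochs$fs, epochs$labels,
    epochs$channel_labels, epochs$channel_roles,
    trial_ids = epochs$trial_ids
  )
}

#' Decimate epochs by block averaging
#'
#' Five-point moving-average decimation realized as non-overlapping block
#' means: each output sample is the mean of `factor` consecutive input samples
#' and the sampling rate is divided by `factor`, so 300 samples at 500 Hz
#' become exactly 60 samples at 100 Hz. Output times are the block means of
#' the input times.
#'
#' @param epochs an [epoch_set()] whose sample count is divisible by `factor`.
#' @param factor decimation factor (default 5).
#' @return the decimated [epoch_set()].
#' @export
decimate_epochs <- function(epochs, factor = 5) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (factor < 1) rlang::abort("`factor` must be >= 1")
  ns <- dim(epochs$data)[2]
  if (ns %% factor != 0) {
    rlang::abort(sprintf("sample count %d not divisible by factor %d", ns, factor))
  }
  n_out <- ns %/% factor
  d <- dim(epochs$data)
  # mean over blocks: reshape samples into (factor, n_out)
  dat <- array(epochs$data, c(d[1], factor, n_out, d[3]))
  dat <- apply(dat, c(1, 3, 4), mean)
  times <- colMeans(matrix(epochs$times, factor, n_out))
  new_fs <- epochs$fs / factor
  # block-averaged time axis keeps 1/new_fs spacing
  epoch_set(
    dat, times, new_fs, epochs$labels,
    epochs$channel_labels, epochs$channel_roles,
    trial_ids = epochs$trial_ids
  )
}

#' Full preprocessing chain
#'
#' Applies, in fixed order: band-pass filter, common average reference,
#' epoching, SOBI-based ocular source cancellation (optional), baseline
#' correction, block decimation.
#'
#' @param recording a [continuous_recording()] with events (and EOG channels
#'   when `sobi = TRUE`).
#' @param low,high band-pass edges, Hz.
#' @param tmin,tmax epoch window, s.
#' @param baseline baseline window, s.
#' @param decim decimation factor.
#' @param sobi logical; run SOBI ocular cancellation (on epoched data by
#'   default)?
#' @param sobi_on `"epochs"` (default) or `"continuous"`: fit the source
#'   decomposition on the epoched or on the continuous data.
#' @param n_remove number of EOG-correlated sources to cancel.
#' @param eog_labels named EOG electrode labels (see [default_eog_labels()]).
#' @return the preprocessed [epoch_set()] (EEG and EOG channels, decimated).
#' @export
preprocess_recording <- function(recording, low = 1, high = 40,
                                 tmin = -0.1, tmax = 0.6,
                                 baseline = c(-0.1, 0), decim = 5,
                                 sobi = TRUE, sobi_on = c("epochs", "continuous"),
                                 n_remove = 2,
                                 eog_labels = default_eog_labels()) {
  sobi_on <- match.arg(sobi_on)
  rec <- bandpass_filter(recording, low, high)
  rec <- common_average_reference(rec)
  epochs <- epoch_recording(rec, tmin, tmax)
  if (sobi) {
    if (sobi_on == "epochs") {
      um <- sobi_unmix(epochs)
    } else {
      um <- sobi_unmix(rec)
    }
    epochs <- remove_eog_sources(um, epochs, n_remove = n_remove, eog_labels = eog_labels)
  }
  epochs <- baseline_correct(epochs, baseline)
  decimate_epochs(epochs, decim)
}
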