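#' Continuous multichannel recording
#'
#' Container for a continuous EEG/EOG recording: a samples x channels matrix in
#' microvolts, a sampling rate, per-channel roles, and stimulation events.
#'
#' @param data numeric matrix, samples x channels (microvolts). Column names,
#'   if present, must agree with `channel_labels`.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector, one per column of `data`.
#' @param channel_roles character vector of `"EEG"` / `"EOG"`, one per channel.
#' @param events data frame / tibble with columns `onset` (1-based sample
#'   index) and `label` (class label, e.g. `"low"` / `"high"`).
#' @return an object of class `continuous_recording`.
#' @export
continuous_recording <- function(data, fs, channel_labels, channel_roles,
                                 events = tibble::tibble(onset = integer(), label = character())) {
  data <- as.matrix(data)
  if (!is.numeric(data)) rlang::abort("`data` must be a numeric matrix")
  if (fs <= 0) rlang::abort("`fs` must be positive")
  if (length(channel_labels) != ncol(data)) {
    rlang::abort("`channel_labels` length must match ncol(data)")
  }
  if (length(channel_roles) != ncol(data)) {
    rlang::abort("`channel_roles` length must match ncol(data)")
  }
  if (!all(channel_roles %in% c("EEG", "EOG"))) {
    rlang::abort("`channel_roles` must be \"EEG\" or \"EOG\"")
  }
  if (sum(channel_roles == "EEG") < 1) rlang::abort("need at least one EEG channel")
  events <- tibble::as_tibble(events)
  if (nrow(events) > 0) {
    if (!all(c("onset", "label") %in% names(events))) {
      rlang::abort("`events` needs columns `onset` and `label`")
    }
    if (any(events$onset < 1L) || any(events$onset > nrow(data))) {
      rlang::abort("event onsets fall outside the recording")
    }
  }
  colnames(data) <- channel_labels
  structure(
    list(
      data = data, fs = fs,
      channel_labels = channel_labels,
      channel_roles = channel_roles,
      events = events
    ),
    class = "continuous_recording"
  )
}

#' @export
print.continuous_recording <- function(x, ...) {
  dur <- nrow(x$data) / x$fs
  cat(sprintf(
    "<continuous_recording> %d channels (%d EEG, %d EOG), %.1f s @ %g Hz, %d events\n",
    ncol(x$data), sum(x$channel_roles == "EEG"), sum(x$channel_roles == "EOG"),
    dur, x$fs, nrow(x$events)
  ))
  invisible(x)
}

n_eeg <- function(x) sum(x$channel_roles == "EEG")
eeg_idx <- function(x) which(x$channel_roles == "EEG")
eog_idx <- function(x) which(x$channel_roles == "EOG")

#' Set of stimulus-locked epochs
#'
#' Container for epoched data: a trials x samples x channels array with a time
#' axis relative to stimulus onset, per-trial class labels and channel metadata.
#'
#' @param data numeric array `c(n_trials, n_samples, n_channels)` in microvolts.
#' @param times numeric vector of sample times in seconds relative to onset,
#'   strictly increasing and uniform at `1/fs`.
#' @param fs sampling rate in Hz.
#' @param labels class label per trial.
#' @param channel_labels,channel_roles channel metadata, as in
#'   [continuous_recording()].
#' @param trial_ids optional integer identity per trial (preserved by
#'   subsetting; used for provenance and cross-validation audits). Defaults to
#'   `1:n_trials`.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, times, fs, labels, channel_labels, channel_roles,
                      trial_ids = NULL) {
  if (length(dim(data)) != 3) rlang::abort("`data` must be a 3-d array (trials x samples x channels)")
  if (length(times) != dim(data)[2]) rlang::abort("`times` length must match sample dimension")
  if (length(labels) != dim(data)[1]) rlang::abort("one label per trial required")
  if (length(channel_labels) != dim(data)[3]) rlang::abort("one channel label per channel required")
  dt <- diff(times)
  if (length(dt) > 0 && (any(dt <= 0) || max(abs(dt - 1 / fs)) > 1e-9)) {
    rlang::abort("`times` must be strictly increasing and uniform at 1/fs")
  }
  trial_ids <- trial_ids %||% seq_len(dim(data)[1])
  dimnames(data) <- list(NULL, NULL, channel_labels)
  structure(
    list(
      data = data, times = times, fs = fs,
      labels = as.character(labels),
      channel_labels = channel_labels,
      channel_roles = channel_roles,
      trial_ids = as.integer(trial_ids)
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "<epoch_set> %d trials (%s), %d samples [%.3f, %.3f] s @ %g Hz, %d channels\n",
    dim(x$data)[1],
    paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
    dim(x$data)[2], min(x$times), max(x$times), x$fs, dim(x$data)[3]
  ))
  invisible(x)
}

#' Subset an epoch set by trial and/or channel
#'
#' @param x an [epoch_set()].
#' @param trials integer or logical trial index.
#' @param channels channel labels or indices.
#' @param ... unused.
#' @return an `epoch_set` with `trial_ids` carried over.
#' @export
subset_epochs <- function(x, trials = NULL, channels = NULL, ...) {
  stopifnot(inherits(x, "epoch_set"))
  trials <- trials %||% seq_len(dim(x$data)[1])
  if (is.null(channels)) {
    ch <- seq_len(dim(x$data)[3])
  } else if (is.character(channels)) {
    ch <- match(channels, x$channel_labels)
    if (anyNA(ch)) {
      rlang::abort(paste0(
        "unknown channel(s): ",
        paste(channels[is.na(ch)], collapse = ", ")
      ))
    }
  } else {
    ch <- channels
  }
  epoch_set(
    x$data[trials, , ch, drop = FALSE], x$times, x$fs,
    x$labels[trials], x$channel_labels[ch], x$channel_roles[ch],
    trial_ids = x$trial_ids[trials]
  )
}

# Epochs restricted to EEG channels (spatial filtering / SOBI operate on these).
eeg_epochs <- function(x) subset_epochs(x, channels = which(x$channel_roles == "EEG"))

# Stack an epoch set into the (trials * samples) x channels matrix used by the
# CCA solve: trials in dataset order, samples contiguous per trial.
stack_epochs <- function(x) {
  d <- dim(x$data)
  out <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[1] * d[2], ncol = d[3])
  colnames(out) <- x$channel_labels
  out
}

#' Convert an epoch set to a long tibble
#'
#' One row per (trial, time, channel); convenient for ggplot2 and dplyr
#' summaries. Beware of size for large epoch sets.
#'
#' @param x an [epoch_set()].
#' @param ... unused.
#' @return a tibble with columns `trial`, `label`, `time`, `channel`,
#'   `amplitude`.
#' @export
as_tibble.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  tibble::tibble(
    trial = rep(seq_len(d[1]), times = d[2] * d[3]),
    label = rep(x$labels, times = d[2] * d[3]),
    time = rep(rep(x$times, each = d[1]), times = d[3]),
    channel = rep(x$channel_labels, each = d[1] * d[2]),
    amplitude = as.vector(x$data)
  )
}
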