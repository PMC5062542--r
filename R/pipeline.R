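#' Stratified random fold assignment
#'
#' Random fivefold partition stratified by class, so every training fold
#' contains both classes even at ~30 trials per class.
#'
#' @param labels class label per trial.
#' @param k number of folds.
#' @param seed optional seed governing the partition.
#' @return integer fold index (1..k) per trial.
#' @export
make_folds <- function(labels, k = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) {
      rlang::abort(sprintf("class %s has fewer trials (%d) than folds (%d)",
                           cl, length(idx), k))
    }
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated workload classification for one processing chain
#'
#' Runs the chain (`"cca"`: template-based CCA spatial filtering + 2-filter
#' features; `"raw"`: concatenated C3/Pz traces) under random stratified
#' k-fold cross-validation with strictly train-fold learning: class
#' templates, the CCA solve, filter selection and the shrinkage-FLDA fit only
#' ever see training trials; the learned filters and classifier are then
#' applied to the held-out fold.
#'
#' @param epochs a preprocessed [epoch_set()] (100 Hz, 60 samples).
#' @param chain `"cca"` or `"raw"`.
#' @param k number of folds (default 5).
#' @param seed seed for the random partition.
#' @param picks raw-chain electrode pair (default `c("C3", "Pz")`).
#' @param n_filters number of CCA filters kept (default 2).
#' @return an object of class `cv_result`: `fold_accuracies`,
#'   `mean_accuracy`, `sd_accuracy` (across folds), `chain`, `seed`, `k`,
#'   `n_trials` (per class), `folds` (held-out trial indices per fold),
#'   `patterns` (CCA chain: spatial patterns averaged across training folds)
#'   and `lambda` (mean shrinkage intensity).
#' @export
run_chain <- function(epochs, chain = c("cca", "raw"), k = 5, seed = NULL,
                      picks = c("C3", "Pz"), n_filters = 2) {
  chain <- match.arg(chain)
  stopifnot(inherits(epochs, "epoch_set"))
  eeg <- eeg_epochs(epochs)
  if (chain == "cca" && dim(eeg$data)[3] < 2) {
    rlang::abort("the CCA chain needs >= 2 EEG channels")
  }
  fold <- make_folds(epochs$labels, k = k, seed = seed)

  fold_acc <- numeric(k)
  n_test <- integer(k)
  lambdas <- numeric(k)
  pattern_sum <- NULL
  for (i in seq_len(k)) {
    tr <- which(fold != i)
    te <- which(fold == i)
    train <- subset_epochs(eeg, trials = tr)
    test <- subset_epochs(eeg, trials = te)
    if (chain == "cca") {
      templates <- class_templates(train)
      ref <- build_reference(train, templates)
      bank <- fit_cca(stack_epochs(train), ref)
      bank <- select_filters(bank, n_filters)
      f_train <- extract_features(train, bank)
      f_test <- extract_features(test, bank)
      pattern_sum <- if (is.null(pattern_sum)) bank$A else pattern_sum + bank$A
    } else {
      f_train <- extract_features_raw(train, picks)
      f_test <- extract_features_raw(test, picks)
    }
    model <- fit_flda(f_train)
    pred <- predict(model, f_test)
    fold_acc[i] <- classification_accuracy(pred, test$labels)
    n_test[i] <- length(te)
    lambdas[i] <- model$lambda_shrink
  }

  structure(
    list(
      fold_accuracies = fold_acc,
      mean_accuracy = mean(fold_acc),
      sd_accuracy = stats::sd(fold_acc),
      chain = chain, seed = seed, k = k,
      n_trials = table(epochs$labels),
      n_test = n_test,
      folds = split(seq_along(fold), fold),
      patterns = if (!is.null(pattern_sum)) pattern_sum / k,
      lambda = mean(lambdas)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> chain = %s: accuracy %.1f%% +/- %.1f (SD over %d folds)\n",
    x$chain, 100 * x$mean_accuracy, 100 * x$sd_accuracy, x$k
  ))
  invisible(x)
}

#' End-to-end workload estimation report
#'
#' Executes the full chain on a continuous recording - band-pass, common
#' average reference, epoching, SOBI ocular cancellation, baseline
#' correction, decimation - then cross-validates both processing chains (with
#' and without CCA spatial filtering) and reports accuracies alongside the
#' binomial chance threshold for the held-out fold size.
#'
#' @param recording a [continuous_recording()] with events and EOG channels,
#'   or the path to a BrainVision header (`.vhdr`).
#' @param k folds (default 5).
#' @param seed seed for the cross-validation partition.
#' @param sobi run the ocular-correction step (default TRUE)?
#' @param alpha significance level for the chance threshold.
#' @param ... further arguments passed to [preprocess_recording()].
#' @return an object of class `workload_report`: `chains` (named list of
#'   [run_chain()] results), `chance_threshold`, `patterns`, `n_epochs`,
#'   `seed`, `config` (preprocessing echo).
#' @export
workload_report <- function(recording, k = 5, seed = NULL, sobi = TRUE,
                            alpha = 0.05, ...) {
  if (is.character(recording)) recording <- read_brainvision(recording)
  stopifnot(inherits(recording, "continuous_recording"))
  if (nrow(recording$events) == 0) rlang::abort("recording has no events")
  if (sobi && sum(recording$channel_roles == "EOG") < 4) {
    rlang::abort("ocular correction needs the 4 EOG channels")
  }
  epochs <- preprocess_recording(recording, sobi = sobi, ...)
  cv_cca <- run_chain(epochs, "cca", k = k, seed = seed)
  cv_raw <- run_chain(epochs, "raw", k = k, seed = seed)
  n_test <- round(dim(epochs$data)[1] / k)
  structure(
    list(
      chains = list(cca = cv_cca, raw = cv_raw),
      chance_threshold = chance_threshold(n_test, alpha),
      n_test_trials = n_test,
      patterns = cv_cca$patterns,
      n_epochs = dim(epochs$data)[1],
      seed = seed,
      config = list(k = k, sobi = sobi, alpha = alpha, fs = epochs$fs,
                    n_samples = dim(epochs$data)[2])
    ),
    class = "workload_report"
  )
}

#' @export
print.workload_report <- function(x, ...) {
  cat("<workload_report>\n")
  cat(sprintf(
    "  CCA chain: %.1f%% +/- %.1f | raw chain: %.1f%% +/- %.1f\n",
    100 * x$chains$cca$mean_accuracy, 100 * x$chains$cca$sd_accuracy,
    100 * x$chains$raw$mean_accuracy, 100 * x$chains$raw$sd_accuracy
  ))
  cat(sprintf(
    "  chance threshold (n = %d, binomial): %.1f%%\n",
    x$n_test_trials, 100 * x$chance_threshold
  ))
  invisible(x)
}
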