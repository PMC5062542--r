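#' Class-average ERP templates
#'
#' Arithmetic mean over the trials of each workload class, per sample and
#' channel.
#'
#' @param epochs an [epoch_set()] with exactly two classes, each with at least
#'   one trial.
#' @return an object of class `template_set`: list with `P` (named list of
#'   samples x channels matrices), `class_ids` (sorted), `times`,
#'   `channel_labels`.
#' @export
class_templates <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  classes <- sort(unique(epochs$labels))
  if (length(classes) != 2) {
    rlang::abort(sprintf("need exactly 2 classes, got %d", length(classes)))
  }
  p <- lapply(classes, function(cl) {
    idx <- which(epochs$labels == cl)
    m <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
    colnames(m) <- epochs$channel_labels
    m
  })
  names(p) <- classes
  structure(
    list(P = p, class_ids = classes, times = epochs$times,
         channel_labels = epochs$channel_labels),
    class = "template_set"
  )
}

#' Build the CCA reference signal
#'
#' The reference Y replicates, for every trial, the average ERP template of
#' that trial's class - the dense realization of Y = D1 P1 + D2 P2 with
#' Toeplitz onset matrices D_i. Rows are stacked exactly like the epoch data
#' (trials in dataset order, samples contiguous per trial).
#'
#' @param epochs an [epoch_set()].
#' @param templates a `template_set` from [class_templates()] with matching
#'   shape.
#' @return an object of class `reference_signal`: list with `Y`
#'   ((trials*samples) x channels) and `class_ids`.
#' @export
build_reference <- function(epochs, templates) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(templates, "template_set"))
  d <- dim(epochs$data)
  p1 <- templates$P[[1]]
  if (nrow(p1) != d[2] || ncol(p1) != d[3]) {
    rlang::abort("template shape does not match the epochs")
  }
  unknown <- setdiff(unique(epochs$labels), templates$class_ids)
  if (length(unknown) > 0) {
    rlang::abort(paste0("label(s) outside the template classes: ",
                        paste(unknown, collapse = ", ")))
  }
  y <- matrix(0, d[1] * d[2], d[3])
  for (j in seq_len(d[1])) {
    y[(j - 1) * d[2] + seq_len(d[2]), ] <- templates$P[[epochs$labels[j]]]
  }
  colnames(y) <- epochs$channel_labels
  structure(list(Y = y, class_ids = templates$class_ids),
            class = "reference_signal")
}

#' Canonical correlation analysis between stacked epochs and the reference
#'
#' Solves CCA through orthonormal bases obtained by singular value
#' decomposition: both matrices are column-centered, reduced to their
#' numerical column space, and the canonical pairs are read off the SVD of the
#' cross-product of the two orthonormal bases. Canonical correlations are
#' returned in descending order; each filter's sign is fixed by forcing the
#' largest-magnitude coefficient of its spatial pattern to be positive, and
#' filters are scaled so the canonical variates have unit variance.
#'
#' @param x stacked epochs, (trials*samples) x channels.
#' @param y the reference: a `reference_signal` or a plain matrix with the
#'   same number of rows.
#' @param rank_tol relative singular-value threshold for the rank truncation
#'   (the common average reference makes EEG data rank-deficient by one).
#' @return an object of class `filter_bank` with `W` (channels x N_f spatial
#'   filters, descending canonical correlation), `A` (spatial patterns,
#'   max-abs-normalized columns), `rho` (canonical correlations),
#'   `y_weights`, `sigma_x` (channel covariance used for the patterns) and
#'   `channel_labels`.
#' @export
fit_cca <- function(x, y, rank_tol = 1e-10) {
  if (inherits(y, "reference_signal")) y <- y$Y
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (nrow(x) != nrow(y)) rlang::abort("X and Y must have the same number of rows")
  n <- nrow(x)
  zero_x <- which(apply(x, 2, stats::sd) == 0)
  if (length(zero_x) > 0) {
    nm <- colnames(x)[zero_x] %||% as.character(zero_x)
    rlang::abort(paste0("zero-variance column(s) in X: ", paste(nm, collapse = ", ")))
  }
  if (any(apply(y, 2, stats::sd) == 0)) {
    # a flat reference channel carries no constraint; it is dropped by the
    # rank truncation below, but an all-zero Y is an error
    if (all(y == y[1, 1])) rlang::abort("reference Y is constant")
  }

  xc <- scale(x, center = TRUE, scale = FALSE)
  yc <- scale(y, center = TRUE, scale = FALSE)
  sx <- svd(xc)
  sy <- svd(yc)
  kx <- sx$d > rank_tol * sx$d[1]
  ky <- sy$d > rank_tol * sy$d[1]
  m <- crossprod(sx$u[, kx, drop = FALSE], sy$u[, ky, drop = FALSE])
  sv <- svd(m)
  nf <- min(sum(kx), sum(ky))
  rho <- pmin(pmax(sv$d[seq_len(nf)], 0), 1)

  w <- sx$v[, kx, drop = FALSE] %*%
    (sv$u[, seq_len(nf), drop = FALSE] / sx$d[kx]) * sqrt(n - 1)
  wy <- sy$v[, ky, drop = FALSE] %*%
    (sv$v[, seq_len(nf), drop = FALSE] / sy$d[ky]) * sqrt(n - 1)

  sigma_x <- crossprod(xc) / (n - 1)
  a <- compute_patterns(w, sigma_x, normalize = TRUE)
  for (k in seq_len(nf)) {
    j <- which.max(abs(a[, k]))
    if (a[j, k] < 0) {
      a[, k] <- -a[, k]
      w[, k] <- -w[, k]
      wy[, k] <- -wy[, k]
    }
  }
  labels <- colnames(x) %||% paste0("ch", seq_len(ncol(x)))
  rownames(w) <- rownames(a) <- labels
  colnames(w) <- colnames(a) <- paste0("w", seq_len(nf))
  structure(
    list(W = w, A = a, rho = rho, y_weights = wy,
         sigma_x = sigma_x, channel_labels = labels),
    class = "filter_bank"
  )
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf(
    "<filter_bank> %d filters over %d channels; rho = %s\n",
    ncol(x$W), nrow(x$W),
    paste(sprintf("%.3f", utils::head(x$rho, 5)), collapse = ", ")
  ))
  invisible(x)
}

#' Keep the k filters with the highest canonical correlations
#'
#' Canonical correlations are already descending, so this keeps the first `k`
#' columns and recomputes the spatial patterns for the retained subset.
#'
#' @param bank a `filter_bank` from [fit_cca()].
#' @param k number of filters to keep (default 2).
#' @return the reduced `filter_bank`.
#' @export
select_filters <- function(bank, k = 2) {
  stopifnot(inherits(bank, "filter_bank"))
  nf <- ncol(bank$W)
  if (k < 1) rlang::abort("`k` must be >= 1 (an empty filter bank is not allowed)")
  if (k > nf) rlang::abort(sprintf("`k` = %d exceeds the %d available filters", k, nf))
  bank$W <- bank$W[, seq_len(k), drop = FALSE]
  bank$rho <- bank$rho[seq_len(k)]
  bank$y_weights <- bank$y_weights[, seq_len(k), drop = FALSE]
  bank$A <- compute_patterns(bank$W, bank$sigma_x, normalize = TRUE)
  rownames(bank$A) <- bank$channel_labels
  colnames(bank$A) <- colnames(bank$W)
  bank
}

#' Spatial patterns of a set of spatial filters
#'
#' For a square, full-rank filter matrix the pattern matrix is the
#' inverse-transpose A = (W^-1)^T. For a rectangular subset of filters the
#' forward-model generalization A = Sigma_X W (W^T Sigma_X W)^-1 is used,
#' which reduces to the inverse-transpose in the square case.
#'
#' @param w channels x N_f filter matrix.
#' @param sigma_x channel covariance of the filtered data (symmetric positive
#'   semidefinite); required when `w` is rectangular.
#' @param normalize scale each pattern column to max-abs 1 (for display)?
#' @return channels x N_f pattern matrix.
#' @export
compute_patterns <- function(w, sigma_x = NULL, normalize = FALSE) {
  w <- as.matrix(w)
  if (nrow(w) == ncol(w) && is.null(sigma_x)) {
    a <- tryCatch(t(solve(w)), error = function(e) {
      rlang::abort("singular filter matrix: patterns undefined")
    })
  } else {
    if (is.null(sigma_x)) rlang::abort("`sigma_x` required for rectangular W")
    g <- crossprod(w, sigma_x %*% w)
    a <- sigma_x %*% w %*% solve(g)
  }
  if (normalize) {
    a <- apply(a, 2, function(col) col / max(abs(col)))
    a <- matrix(a, nrow = nrow(w))
  }
  a
}

new_feature_matrix <- function(x, labels, trial_ids = NULL) {
  structure(
    list(x = x, labels = as.character(labels),
         trial_ids = trial_ids %||% seq_len(nrow(x))),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d trials x %d features\n", nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Single-trial features from two spatial filters
#'
#' Projects each epoch onto the two selected filters ("virtual electrodes")
#' and concatenates the two 60-sample traces: all samples of the first filter,
#' then all samples of the second, giving a 120-dimensional feature vector per
#' trial.
#'
#' @param epochs a decimated [epoch_set()] with exactly 60 samples.
#' @param bank a `filter_bank` with exactly 2 filters (see [select_filters()]).
#' @return a `feature_matrix` (trials x 120) carrying the trial labels.
#' @export
extract_features <- function(epochs, bank) {
  stopifnot(inherits(epochs, "epoch_set"), inherits(bank, "filter_bank"))
  if (ncol(bank$W) != 2) rlang::abort("feature extraction requires exactly 2 filters")
  ee <- subset_epochs(epochs, channels = bank$channel_labels)
  d <- dim(ee$data)
  if (d[2] != 60) {
    rlang::abort(sprintf(
      "feature contract violated: expected 60 samples per epoch (100 Hz, 0.6 s), got %d",
      d[2]
    ))
  }
  out <- matrix(0, d[1], 2 * d[2])
  for (j in seq_len(d[1])) {
    z <- matrix(ee$data[j, , ], d[2], d[3]) %*% bank$W
    out[j, ] <- as.vector(z)
  }
  new_feature_matrix(out, ee$labels, ee$trial_ids)
}

#' Single-trial features from two raw electrodes
#'
#' The spatial-filter-free counterpart of [extract_features()]: concatenates
#' the raw traces of two electrodes (C3 and Pz by default, picked for their
#' proximity to the average discriminative patterns), preserving the same
#' 120-feature layout.
#'
#' @param epochs a decimated [epoch_set()] with exactly 60 samples.
#' @param picks two channel labels (default `c("C3", "Pz")`).
#' @return a `feature_matrix` (trials x 120).
#' @export
extract_features_raw <- function(epochs, picks = c("C3", "Pz")) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (length(picks) != 2) rlang::abort("`picks` must name exactly 2 channels")
  ee <- subset_epochs(epochs, channels = picks) # errors on unknown labels
  d <- dim(ee$data)
  if (d[2] != 60) {
    rlang::abort(sprintf(
      "feature contract violated: expected 60 samples per epoch, got %d", d[2]
    ))
  }
  out <- matrix(0, d[1], 2 * d[2])
  for (j in seq_len(d[1])) {
    out[j, ] <- as.vector(matrix(ee$data[j, , ], d[2], d[3]))
  }
  new_feature_matrix(out, ee$labels, ee$trial_ids)
}
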