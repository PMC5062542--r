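#' Second-Order Blind Identification (SOBI)
#'
#' Blind source separation by whitening followed by approximate joint
#' diagonalization of time-lagged covariance matrices with Jacobi rotations.
#' SOBI assumes mutually uncorrelated sources with distinct temporal
#' autocorrelation - a weaker assumption than the mutual independence required
#' by ICA, and a good match for electrophysiological data.
#'
#' When `x` is an [epoch_set()], lagged covariances are accumulated within
#' epochs only (no products across epoch boundaries). Only EEG channels enter
#' the decomposition. Whitening truncates at the numerical rank, so data made
#' rank-deficient by the common average reference yield one source fewer than
#' channels.
#'
#' @param x an [epoch_set()] or [continuous_recording()].
#' @param lags positive sample lags for the lagged covariances; at least two
#'   distinct lags are required. Default 1:50 spans 2-100 ms at 500 Hz.
#' @param tol Jacobi stopping tolerance on the rotation sine (default 1e-8).
#' @param max_sweeps maximum Jacobi sweeps (default 200).
#' @param rank_tol relative eigenvalue threshold for the whitening rank cut.
#' @return an object of class `sobi_unmix` with fields `unmixing` (sources x
#'   channels), `mixing` (channels x sources, pseudo-inverse of the unmixing),
#'   `source_timecourses` (sources x samples, unit variance, ordered by
#'   explained channel-space variance), `center` (channel means removed before
#'   the fit), `lags_used`, `diagonalization_residual` (off-diagonal fraction
#'   of the rotated lagged covariances) and `sweep_residuals`.
#' @export
sobi_unmix <- function(x, lags = 1:50, tol = 1e-8, max_sweeps = 200,
                       rank_tol = 1e-10) {
  lags <- as.integer(lags)
  if (length(unique(lags[lags > 0])) < 2) {
    rlang::abort("joint diagonalization needs >= 2 distinct positive lags")
  }
  lags <- sort(unique(lags[lags > 0]))

  if (inherits(x, "epoch_set")) {
    ee <- eeg_epochs(x)
    d <- dim(ee$data)
    segments <- lapply(seq_len(d[1]), function(j) {
      matrix(ee$data[j, , ], d[2], d[3])
    })
    ch_labels <- ee$channel_labels
  } else if (inherits(x, "continuous_recording")) {
    segments <- list(x$data[, eeg_idx(x), drop = FALSE])
    ch_labels <- x$channel_labels[eeg_idx(x)]
  } else {
    rlang::abort("`x` must be an epoch_set or continuous_recording")
  }
  nch <- length(ch_labels)
  if (nch < 2) rlang::abort("SOBI needs >= 2 EEG channels")
  total <- sum(vapply(segments, nrow, integer(1)))
  if (total <= max(lags) * 10) {
    rlang::abort("too few samples for the requested lag set (need > 10 * max lag)")
  }

  xall <- do.call(rbind, segments)
  ctr <- colMeans(xall)
  xall <- sweep(xall, 2, ctr)

  # a perfectly duplicated (or inverted) channel makes the problem degenerate
  cc <- suppressWarnings(stats::cor(xall))
  cc[!is.finite(cc)] <- 0
  diag(cc) <- 0
  if (any(abs(cc) > 1 - 1e-10)) {
    ij <- which(abs(cc) > 1 - 1e-10, arr.ind = TRUE)[1, ]
    rlang::abort(sprintf(
      "rank-deficient covariance: channels %s and %s are perfectly correlated",
      ch_labels[ij[1]], ch_labels[ij[2]]
    ))
  }

  c0 <- crossprod(xall) / nrow(xall)
  eg <- eigen(c0, symmetric = TRUE)
  keep <- eg$values > rank_tol * eg$values[1]
  if (sum(keep) < 2) rlang::abort("covariance numerically rank < 2")
  dvals <- eg$values[keep]
  u <- eg$vectors[, keep, drop = FALSE]
  w_white <- diag(1 / sqrt(dvals), nrow = length(dvals)) %*% t(u)
  r <- nrow(w_white)

  # whitened, segment-wise lagged covariances (symmetrized)
  z_segs <- lapply(segments, function(s) sweep(s, 2, ctr) %*% t(w_white))
  cs <- array(0, c(r, r, length(lags)))
  for (k in seq_along(lags)) {
    tau <- lags[k]
    acc <- matrix(0, r, r)
    npairs <- 0
    for (z in z_segs) {
      nz <- nrow(z)
      if (nz <= tau) next
      acc <- acc + crossprod(
        z[seq_len(nz - tau), , drop = FALSE],
        z[tau + seq_len(nz - tau), , drop = FALSE]
      )
      npairs <- npairs + (nz - tau)
    }
    acc <- acc / npairs
    cs[, , k] <- 0.5 * (acc + t(acc))
  }

  jd <- joint_diagonalize(cs, tol = tol, max_sweeps = max_sweeps)
  unmixing <- t(jd$v) %*% w_white # sources x channels
  mixing <- u %*% diag(sqrt(dvals), nrow = length(dvals)) %*% jd$v

  # order by explained channel-space variance (sources are unit variance)
  ord <- order(colSums(mixing^2), decreasing = TRUE)
  unmixing <- unmixing[ord, , drop = FALSE]
  mixing <- mixing[, ord, drop = FALSE]
  for (k in seq_len(r)) {
    j <- which.max(abs(mixing[, k]))
    if (mixing[j, k] < 0) {
      mixing[, k] <- -mixing[, k]
      unmixing[k, ] <- -unmixing[k, ]
    }
  }
  colnames(mixing) <- rownames(unmixing) <- paste0("S", seq_len(r))
  colnames(unmixing) <- rownames(mixing) <- ch_labels

  structure(
    list(
      unmixing = unmixing, mixing = mixing,
      source_timecourses = unmixing %*% t(xall),
      center = ctr, channel_labels = ch_labels,
      lags_used = lags,
      diagonalization_residual = jd$residual,
      sweep_residuals = jd$sweep_residuals,
      n_sweeps = jd$n_sweeps
    ),
    class = "sobi_unmix"
  )
}

#' @export
print.sobi_unmix <- function(x, ...) {
  cat(sprintf(
    "<sobi_unmix> %d sources from %d channels, %d lags, residual %.2e (%d sweeps)\n",
    nrow(x$unmixing), ncol(x$unmixing), length(x$lags_used),
    x$diagonalization_residual, x$n_sweeps
  ))
  invisible(x)
}

# Approximate joint diagonalization of symmetric matrices by Jacobi rotations
# (Cardoso & Souloumiac angle formula). Returns the orthogonal rotation `v`
# such that t(v) %*% C_k %*% v is jointly near-diagonal.
joint_diagonalize <- function(cs, tol = 1e-8, max_sweeps = 200) {
  m <- dim(cs)[1]
  v <- diag(m)
  off_fraction <- function(a) {
    tot <- sum(a^2)
    diagsq <- sum(apply(a, 3, function(x) sum(diag(x)^2)))
    if (tot == 0) return(0)
    (tot - diagsq) / tot
  }
  sweep_res <- numeric(0)
  n_sweeps <- 0
  repeat {
    n_sweeps <- n_sweeps + 1
    max_s <- 0
    for (p in seq_len(m - 1)) {
      for (q in seq.int(p + 1, m)) {
        h1 <- cs[p, p, ] - cs[q, q, ]
        h2 <- cs[p, q, ] + cs[q, p, ]
        ton <- sum(h1 * h1) - sum(h2 * h2)
        toff <- 2 * sum(h1 * h2)
        theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
        cth <- cos(theta)
        sth <- sin(theta)
        if (abs(sth) > tol) {
          max_s <- max(max_s, abs(sth))
          rp <- cs[p, , , drop = FALSE]
          rq <- cs[q, , , drop = FALSE]
          cs[p, , ] <- cth * rp[1, , ] + sth * rq[1, , ]
          cs[q, , ] <- cth * rq[1, , ] - sth * rp[1, , ]
          cp <- cs[, p, , drop = FALSE]
          cq <- cs[, q, , drop = FALSE]
          cs[, p, ] <- cth * cp[, 1, ] + sth * cq[, 1, ]
          cs[, q, ] <- cth * cq[, 1, ] - sth * cp[, 1, ]
          vp <- v[, p]
          v[, p] <- cth * vp + sth * v[, q]
          v[, q] <- cth * v[, q] - sth * vp
        }
      }
    }
    sweep_res <- c(sweep_res, off_fraction(cs))
    if (max_s < tol || n_sweeps >= max_sweeps) break
  }
  list(v = v, residual = off_fraction(cs), sweep_residuals = sweep_res,
       n_sweeps = n_sweeps)
}

#' Cancel the EOG-correlated sources
#'
#' Identifies, among the SOBI sources, the one most correlated (absolute
#' Pearson r on concatenated epoch timecourses) with the vertical bipolar EOG
#' (above - below the left eye) and the one most correlated with the
#' horizontal bipolar EOG (left - right outer canthus); when both picks
#' coincide the horizontal pick falls back to the next-best source. The epochs
#' are then reconstructed from the remaining sources; EOG channels and epoch
#' geometry are untouched.
#'
#' @param result a [sobi_unmix()] fit.
#' @param epochs the [epoch_set()] to clean (must contain the EOG channels and
#'   the EEG channels the fit was computed on).
#' @param n_remove number of sources to cancel (default 2: one vertical, one
#'   horizontal). `0` returns the input unchanged; beyond 2, additional
#'   sources are removed in decreasing order of their strongest EOG
#'   correlation.
#' @param eog_labels named EOG electrode labels (see [default_eog_labels()]).
#' @return the cleaned [epoch_set()]; attribute `removed_sources` records the
#'   cancelled source indices and their EOG correlations.
#' @export
remove_eog_sources <- function(result, epochs, n_remove = 2,
                               eog_labels = default_eog_labels()) {
  stopifnot(inherits(result, "sobi_unmix"), inherits(epochs, "epoch_set"))
  n_sources <- nrow(result$unmixing)
  if (n_remove > n_sources) rlang::abort("`n_remove` exceeds the number of sources")
  if (n_remove == 0) return(epochs)
  missing <- setdiff(unname(eog_labels), epochs$channel_labels)
  if (length(missing) > 0) {
    rlang::abort(paste0("missing EOG channel(s): ", paste(missing, collapse = ", ")))
  }

  ee <- subset_epochs(epochs, channels = result$channel_labels)
  x <- sweep(stack_epochs(ee), 2, result$center)
  s <- x %*% t(result$unmixing) # (trials*samples) x sources

  eog <- subset_epochs(epochs, channels = unname(eog_labels))
  eogm <- stack_epochs(eog)
  veog <- eogm[, match(eog_labels[["above"]], colnames(eogm))] -
    eogm[, match(eog_labels[["below"]], colnames(eogm))]
  heog <- eogm[, match(eog_labels[["left"]], colnames(eogm))] -
    eogm[, match(eog_labels[["right"]], colnames(eogm))]
  if (stats::sd(veog) == 0 || stats::sd(heog) == 0) {
    rlang::abort("constant EOG derivation: correlation undefined")
  }

  r_v <- abs(as.vector(stats::cor(s, veog)))
  r_h <- abs(as.vector(stats::cor(s, heog)))
  pick_v <- which.max(r_v)
  drop_idx <- pick_v
  if (n_remove >= 2) {
    cand_h <- order(r_h, decreasing = TRUE)
    pick_h <- cand_h[cand_h != pick_v][1]
    drop_idx <- c(drop_idx, pick_h)
  }
  if (n_remove > 2) {
    rest <- setdiff(seq_len(n_sources), drop_idx)
    extra <- rest[order(pmax(r_v, r_h)[rest], decreasing = TRUE)]
    drop_idx <- c(drop_idx, utils::head(extra, n_remove - 2))
  }

  keep <- setdiff(seq_len(n_sources), drop_idx)
  clean <- s[, keep, drop = FALSE] %*% t(result$mixing[, keep, drop = FALSE])
  clean <- sweep(clean, 2, result$center, "+")

  d <- dim(ee$data)
  arr <- aperm(array(clean, c(d[2], d[1], d[3])), c(2, 1, 3))
  out <- epochs
  ch <- match(result$channel_labels, epochs$channel_labels)
  out$data[, , ch] <- arr
  attr(out, "removed_sources") <- tibble::tibble(
    source = drop_idx,
    r_veog = r_v[drop_idx],
    r_heog = r_h[drop_idx]
  )
  out
}

#' Amari index between an estimated unmixing and the true mixing
#'
#' Permutation- and scale-invariant distance on the product
#' `P = unmixing %*% true_mixing`; 0 means perfect source recovery, values
#' below ~0.05 indicate excellent separation.
#'
#' @param p the product matrix (square).
#' @return a non-negative scalar.
#' @export
amari_index <- function(p) {
  p <- abs(p)
  m <- nrow(p)
  rowterm <- sum(rowSums(p / apply(p, 1, max)) - 1)
  colterm <- sum(colSums(t(t(p) / apply(p, 2, max))) - 1)
  (rowterm + colterm) / (2 * m * (m - 1))
}
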