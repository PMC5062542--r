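`%||%` <- function(a, b) if (is.null(a)) b else a

# Small problem sizes for unit tests; the default study-sized configuration is
# exercised in test-acceptance.R.
quick_cfg <- function(..., n_trials_per_class = 12, iti_range = c(1.5, 3),
                      blink_rate = 0, saccade_rate = 0) {
  sim_config(
    n_trials_per_class = n_trials_per_class, iti_range = iti_range,
    blink_rate = blink_rate, saccade_rate = saccade_rate, ...
  )
}

# Epoch set built straight from an array (trials x samples x channels).
toy_epochs <- function(data, fs = 100, labels = NULL, roles = NULL, t0 = 0) {
  d <- dim(data)
  labels <- labels %||% rep(c("low", "high"), length.out = d[1])
  epoch_set(
    data,
    times = t0 + seq_len(d[2]) / fs - 1 / fs,
    fs = fs,
    labels = labels,
    channel_labels = paste0("ch", seq_len(d[3])),
    channel_roles = roles %||% rep("EEG", d[3])
  )
}

# Separable Gaussian epochs at the decimated geometry (60 samples, 100 Hz):
# class "high" gets a mean offset on channel 1 over samples 10:20.
separable_epochs <- function(n_per_class = 15, nch = 4, effect = 2, sd = 1,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("low", "high"), each = n_per_class)
  dat <- array(rnorm(n * 60 * nch, sd = sd), c(n, 60, nch))
  dat[labels == "high", 10:20, 1] <- dat[labels == "high", 10:20, 1] + effect
  ep <- toy_epochs(dat, fs = 100, labels = labels)
  ep$channel_labels <- c("C3", "Pz", paste0("ch", seq_len(nch - 2)))[seq_len(nch)]
  dimnames(ep$data)[[3]] <- ep$channel_labels
  ep
}

# Brute-force CCA via the generalized eigenproblem assembled from raw
# covariance blocks - the independent oracle for fit_cca.
cca_bruteforce <- function(x, y) {
  xc <- scale(x, scale = FALSE)
  yc <- scale(y, scale = FALSE)
  n <- nrow(xc)
  sxx <- crossprod(xc) / (n - 1)
  syy <- crossprod(yc) / (n - 1)
  sxy <- crossprod(xc, yc) / (n - 1)
  m <- solve(sxx, sxy) %*% solve(syy, t(sxy))
  eg <- eigen(m)
  ord <- order(Re(eg$values), decreasing = TRUE)
  list(
    rho = sqrt(pmax(Re(eg$values[ord]), 0)),
    w = Re(eg$vectors[, ord, drop = FALSE])
  )
}

# cosine similarity up to sign
abs_cosine <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
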