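#' Conventional auditory component search windows
#'
#' Default peak-search windows (seconds) and polarities for the auditory
#' evoked components. These are conventional AEP windows, configurable per
#' call - not measured values.
#'
#' @return tibble with columns `component`, `lower`, `upper`, `polarity`.
#' @export
default_component_windows <- function() {
  tibble::tribble(
    ~component, ~lower, ~upper, ~polarity,
    "P1", 0.040, 0.120, "positive",
    "N1", 0.080, 0.180, "negative",
    "P2", 0.150, 0.280, "positive",
    "N2", 0.180, 0.350, "negative",
    "P3", 0.250, 0.550, "positive"
  )
}

#' Measure a component peak on an ERP trace
#'
#' Signed extremum within the search window: the maximum for positive
#' components, the minimum for negative ones; the latency is the time of that
#' extremum, with plateau ties resolved to the earliest sample.
#'
#' @param trace numeric ERP trace (one channel), microvolts.
#' @param times sample times in seconds, same length as `trace`.
#' @param window `c(lower, upper)` search window in seconds (inclusive).
#' @param polarity `"positive"` or `"negative"`.
#' @param component,electrode optional labels carried into the output.
#' @return one-row tibble: `component`, `electrode`, `amplitude` (uV),
#'   `latency` (s).
#' @export
peak_measure <- function(trace, times, window,
                         polarity = c("positive", "negative"),
                         component = NA_character_, electrode = NA_character_) {
  polarity <- match.arg(polarity)
  if (length(trace) != length(times)) rlang::abort("`trace` and `times` lengths differ")
  in_win <- which(times >= window[1] & times <= window[2])
  if (length(in_win) == 0) rlang::abort("empty search window")
  seg <- trace[in_win]
  k <- if (polarity == "positive") which.max(seg) else which.min(seg)
  tibble::tibble(
    component = component, electrode = electrode,
    amplitude = seg[k], latency = times[in_win[k]]
  )
}

#' Measure all components of an ERP at one electrode
#'
#' @param erp samples x channels class-average ERP matrix (or a single trace).
#' @param times sample times, seconds.
#' @param electrode channel label to measure (column of `erp`); ignored when
#'   `erp` is a vector.
#' @param windows component window table, see [default_component_windows()].
#' @return tibble with one row per component.
#' @export
measure_components <- function(erp, times, electrode = "Pz",
                               windows = default_component_windows()) {
  trace <- if (is.matrix(erp)) {
    j <- match(electrode, colnames(erp))
    if (is.na(j)) rlang::abort(paste0("electrode not found: ", electrode))
    erp[, j]
  } else {
    as.numeric(erp)
  }
  purrr::pmap_dfr(windows, function(component, lower, upper, polarity) {
    peak_measure(trace, times, c(lower, upper), polarity,
      component = component, electrode = electrode
    )
  })
}

#' Paired condition comparison
#'
#' Paired t-test on the per-subject differences; for a two-level
#' repeated-measures design the ANOVA F statistic equals t^2 with
#' df = (1, n - 1), so both are reported.
#'
#' @param x,y per-subject values for the two conditions, equal length n >= 2.
#' @return one-row tibble: `t`, `F`, `df1`, `df2`, `p` (two-sided).
#' @export
paired_compare <- function(x, y) {
  if (length(x) != length(y)) rlang::abort("`x` and `y` lengths differ")
  n <- length(x)
  if (n < 2) rlang::abort("need n >= 2 pairs")
  d <- x - y
  if (stats::var(d) == 0) {
    if (all(d == 0)) {
      return(tibble::tibble(t = 0, F = 0, df1 = 1, df2 = n - 1, p = 1))
    }
    rlang::abort("zero variance of the paired differences")
  }
  tt <- mean(d) / (stats::sd(d) / sqrt(n))
  tibble::tibble(
    t = tt, F = tt^2, df1 = 1, df2 = n - 1,
    p = 2 * stats::pt(-abs(tt), df = n - 1)
  )
}

#' Behavioral performance score
#'
#' Response time divided by the proportion of correct responses; higher means
#' worse performance.
#'
#' @param rt response time, seconds.
#' @param prop_correct proportion of correct responses, in (0, 1].
#' @return numeric score (vectorized).
#' @export
behavioral_score <- function(rt, prop_correct) {
  if (any(prop_correct <= 0) || any(prop_correct > 1)) {
    rlang::abort("`prop_correct` must be in (0, 1]")
  }
  rt / prop_correct
}

#' Binomial chance-level threshold for decoding accuracy
#'
#' The minimum accuracy statistically distinguishable from 50% guessing:
#' `m / n` where m is the smallest correct-count with cumulative binomial
#' probability `>= 1 - alpha` under Binomial(n, 0.5), computed by exhaustive
#' summation of the binomial probabilities. At n = 20 and alpha = 0.05 this
#' gives 0.70 - accuracies above 70% on 20 trials are significant at p < .05.
#'
#' @param n_trials number of test trials (>= 1).
#' @param alpha significance level in (0, 1).
#' @return threshold accuracy as a fraction in `[0, 1]`.
#' @export
chance_threshold <- function(n_trials, alpha = 0.05) {
  if (n_trials < 1) rlang::abort("`n_trials` must be >= 1")
  if (alpha <= 0 || alpha >= 1) rlang::abort("`alpha` must be in (0, 1)")
  probs <- stats::dbinom(0:n_trials, n_trials, 0.5)
  cdf <- cumsum(probs)
  m <- which(cdf >= 1 - alpha)[1] - 1 # counts are 0-based
  m / n_trials
}
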