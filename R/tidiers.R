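#' Tidy a cross-validation result
#'
#' @param x a `cv_result` from [run_chain()].
#' @param ... unused.
#' @return tibble with one row per fold: `chain`, `fold`, `n_test`,
#'   `accuracy`.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    chain = x$chain,
    fold = seq_along(x$fold_accuracies),
    n_test = x$n_test,
    accuracy = x$fold_accuracies
  )
}

#' @rdname tidy.cv_result
#' @return `glance()` returns a one-row summary: `chain`, `mean_accuracy`,
#'   `sd_accuracy`, `k`, `lambda`, `seed`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    chain = x$chain,
    mean_accuracy = x$mean_accuracy,
    sd_accuracy = x$sd_accuracy,
    k = x$k,
    lambda = x$lambda,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a fitted discriminant
#'
#' @param x an `flda_model`.
#' @param ... unused.
#' @return tibble with one row per feature: `feature`, `weight`.
#' @export
tidy.flda_model <- function(x, ...) {
  tibble::tibble(feature = seq_along(x$weights), weight = x$weights)
}

#' @rdname tidy.flda_model
#' @export
glance.flda_model <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$weights),
    lambda_shrink = x$lambda_shrink,
    bias = x$bias,
    class_positive = x$classes[1],
    class_negative = x$classes[2]
  )
}

#' Tidy a filter bank
#'
#' @param x a `filter_bank`.
#' @param ... unused.
#' @return tibble in long format: `channel`, `filter`, `weight` (filter
#'   coefficients) and `pattern` (forward-model weights).
#' @export
tidy.filter_bank <- function(x, ...) {
  tibble::tibble(
    channel = rep(rownames(x$W), times = ncol(x$W)),
    filter = rep(colnames(x$W), each = nrow(x$W)),
    weight = as.vector(x$W),
    pattern = as.vector(x$A),
    rho = rep(x$rho, each = nrow(x$W))
  )
}

#' @rdname tidy.cv_result
#' @export
tidy.workload_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$chains, tidy))
}

#' @rdname tidy.cv_result
#' @export
glance.workload_report <- function(x, ...) {
  dplyr::bind_rows(lapply(x$chains, glance)) |>
    dplyr::mutate(
      chance_threshold = x$chance_threshold,
      n_epochs = x$n_epochs
    )
}
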