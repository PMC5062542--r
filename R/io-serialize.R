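#' Serialize an LDA model to JSON
#'
#' Stores weights, bias, shrinkage intensity, class means and the label map -
#' enough to audit a fitted classifier or re-apply it elsewhere.
#'
#' @param model an `flda_model`.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_lda_json <- function(model, path) {
  stopifnot(inherits(model, "flda_model"))
  jsonlite::write_json(
    list(
      weights = model$weights, bias = model$bias,
      lambda_shrink = model$lambda_shrink,
      classes = model$classes,
      class_means = model$class_means
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_lda_json
#' @export
read_lda_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      weights = as.numeric(obj$weights), bias = obj$bias,
      lambda_shrink = obj$lambda_shrink,
      class_means = lapply(obj$class_means, as.numeric),
      classes = obj$classes
    ),
    class = "flda_model"
  )
}

#' Export spatial patterns as CSV
#'
#' Long format (`channel`, `filter`, `weight`) suitable for topographic
#' plotting by external tools.
#'
#' @param bank a `filter_bank` (or a `cv_result` with averaged patterns).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_patterns_csv <- function(bank, path) {
  a <- if (inherits(bank, "filter_bank")) bank$A else bank$patterns
  if (is.null(a)) rlang::abort("no patterns to export")
  df <- tibble::tibble(
    channel = rep(rownames(a), times = ncol(a)),
    filter = rep(colnames(a) %||% paste0("w", seq_len(ncol(a))), each = nrow(a)),
    weight = as.vector(a)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a peak-measure table as CSV
#'
#' @param peaks tibble from [measure_components()] (optionally with added
#'   `subject` / `condition` columns).
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_peaks_csv <- function(peaks, path) {
  utils::write.csv(peaks, path, row.names = FALSE)
  invisible(path)
}
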