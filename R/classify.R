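#' Analytic shrinkage estimate of a covariance matrix
#'
#' Regularizes the empirical covariance toward a scaled identity,
#' `Sigma_hat = (1 - lambda) * S + lambda * nu * I` with `nu = trace(S)/p`,
#' using the analytic (Ledoit-Wolf / Schafer-Strimmer) shrinkage intensity
#' clipped to `[0, 1]`. With any `lambda > 0` the estimate is positive
#' definite even when p > n, which is what makes 120-dimensional LDA on a few
#' dozen trials feasible. The trace is preserved for every lambda.
#'
#' @param x numeric matrix, observations x features, already centered (for
#'   pooled class-conditional covariance, center each class at its own mean
#'   first - [fit_flda()] does this).
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`; `NULL`
#'   (default) uses the analytic value.
#' @return list with `sigma` (p x p), `lambda`, and `nu`.
#' @export
shrinkage_covariance <- function(x, lambda = NULL) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2) rlang::abort("need at least 2 observations")
  s <- crossprod(x) / (n - 1)
  nu <- sum(diag(s)) / p
  if (nu == 0) {
    # zero within-class scatter (e.g., noise-free templates): fall back to the
    # identity so the discriminant reduces to the nearest-class-mean rule
    return(list(sigma = diag(1, p), lambda = 1, nu = 1))
  }
  if (is.null(lambda)) {
    # Var-hat of the entries of S from the per-observation outer products
    sum_w <- crossprod(x) # sum_k x_ki x_kj
    sum_w2 <- crossprod(x^2) # sum_k (x_ki x_kj)^2
    var_s <- (n / (n - 1)^3) * (sum_w2 - sum_w^2 / n)
    target <- diag(nu, p)
    denom <- sum((s - target)^2)
    lambda <- if (denom > 0) sum(var_s) / denom else 1
    lambda <- min(max(lambda, 0), 1)
  } else {
    if (lambda < 0 || lambda > 1) rlang::abort("`lambda` must be in [0, 1]")
  }
  sigma <- (1 - lambda) * s + lambda * diag(nu, p)
  list(sigma = sigma, lambda = lambda, nu = nu)
}

#' Fit a shrinkage-regularized Fisher linear discriminant
#'
#' Pooled class-centered covariance with analytic shrinkage, weight vector
#' `w = Sigma_hat^-1 (mu1 - mu2)` and bias `w' (mu1 + mu2) / 2` (equal class
#' priors; the experimental design is balanced). The first class in sorted
#' label order sits on the positive side of the decision function.
#'
#' @param features a `feature_matrix` (see [extract_features()]), or a plain
#'   matrix together with `labels`.
#' @param labels class labels when `features` is a matrix.
#' @param lambda optional fixed shrinkage intensity (default: analytic).
#' @param pooling `"pooled"` (default; one covariance of all class-centered
#'   trials) or `"average"` (mean of the per-class shrinkage estimates).
#' @return an object of class `flda_model`: `weights`, `bias`,
#'   `lambda_shrink`, `class_means`, `classes`.
#' @export
fit_flda <- function(features, labels = NULL, lambda = NULL,
                     pooling = c("pooled", "average")) {
  pooling <- match.arg(pooling)
  if (inherits(features, "feature_matrix")) {
    x <- features$x
    labels <- features$labels
  } else {
    x <- as.matrix(features)
  }
  if (is.null(labels)) rlang::abort("`labels` required")
  if (any(!is.finite(x))) rlang::abort("non-finite feature values")
  classes <- sort(unique(labels))
  if (length(classes) != 2) rlang::abort("exactly 2 classes required")
  idx1 <- which(labels == classes[1])
  idx2 <- which(labels == classes[2])
  if (length(idx1) == 0 || length(idx2) == 0) rlang::abort("a class has no trials")
  mu1 <- colMeans(x[idx1, , drop = FALSE])
  mu2 <- colMeans(x[idx2, , drop = FALSE])

  if (pooling == "pooled") {
    xc <- rbind(
      sweep(x[idx1, , drop = FALSE], 2, mu1),
      sweep(x[idx2, , drop = FALSE], 2, mu2)
    )
    sh <- shrinkage_covariance(xc, lambda = lambda)
  } else {
    s1 <- shrinkage_covariance(sweep(x[idx1, , drop = FALSE], 2, mu1), lambda = lambda)
    s2 <- shrinkage_covariance(sweep(x[idx2, , drop = FALSE], 2, mu2), lambda = lambda)
    sh <- list(sigma = (s1$sigma + s2$sigma) / 2,
               lambda = mean(c(s1$lambda, s2$lambda)))
  }

  w <- solve(sh$sigma, mu1 - mu2)
  b <- sum(w * (mu1 + mu2)) / 2
  structure(
    list(
      weights = as.numeric(w), bias = b, lambda_shrink = sh$lambda,
      class_means = list(mu1, mu2) |> stats::setNames(classes),
      classes = classes
    ),
    class = "flda_model"
  )
}

#' @export
print.flda_model <- function(x, ...) {
  cat(sprintf(
    "<flda_model> %d features, classes %s vs %s, lambda = %.3f\n",
    length(x$weights), x$classes[1], x$classes[2], x$lambda_shrink
  ))
  invisible(x)
}

#' Predict workload class
#'
#' Assigns labels by the sign of the decision value `w'f - bias`; an exact
#' zero goes to the first class (documented tie-break).
#'
#' @param object an `flda_model`.
#' @param features a `feature_matrix` or plain matrix with the model's feature
#'   dimension.
#' @param type `"class"` (default) or `"score"` for raw decision values.
#' @param ... unused.
#' @return character vector of labels, or numeric scores.
#' @export
predict.flda_model <- function(object, features, type = c("class", "score"), ...) {
  type <- match.arg(type)
  x <- if (inherits(features, "feature_matrix")) features$x else as.matrix(features)
  if (ncol(x) != length(object$weights)) {
    rlang::abort(sprintf(
      "feature dimension %d does not match the model's %d",
      ncol(x), length(object$weights)
    ))
  }
  score <- as.numeric(x %*% object$weights) - object$bias
  if (type == "score") return(score)
  ifelse(score >= 0, object$classes[1], object$classes[2])
}

#' Classification accuracy
#'
#' @param predicted,truth label vectors of equal, nonzero length.
#' @return fraction of exact agreements in `[0, 1]`.
#' @export
classification_accuracy <- function(predicted, truth) {
  if (length(predicted) == 0) rlang::abort("empty input")
  if (length(predicted) != length(truth)) rlang::abort("length mismatch")
  mean(predicted == truth)
}
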