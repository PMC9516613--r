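# Cross-cohort fixed-effect meta-regression: weighted least squares of
# cohort-level estimates on a cohort-level covariate (mean age), with
# weights from the reported standard errors.

#' Fit an inverse-SE-weighted linear meta-regression
#'
#' Fixed-effect weighted least squares of `estimate` on `covariate`.
#' The default weight scheme is the standard inverse-variance weighting
#' `w = 1/se^2`, for which the coefficient covariance is the inverse
#' weighted normal-equation matrix `(X'WX)^-1`.  The literal
#' `inverse_se` scheme (`w = 1/se`) is also provided; its coefficient
#' covariance uses the sandwich form
#' `(X'WX)^-1 X'W V W X (X'WX)^-1` with `V = diag(se^2)`, which reduces
#' to `(X'WX)^-1` under inverse-variance weights.
#'
#' @param estimate Numeric vector of cohort-level estimates (e.g. mean
#'   cluster scores).
#' @param se Positive standard errors of the estimates.
#' @param covariate Numeric cohort-level covariate (e.g. mean age in
#'   years); at least two distinct values.
#' @param weights `"inverse_variance"` (default) or `"inverse_se"`.
#' @return Object of class `meta_regression_fit` with fields `slope`,
#'   `intercept`, `slope_se`, `intercept_se`, `slope_ci95`,
#'   `weights_used`, `residuals`, `fitted`.
#' @export
fit_meta_regression <- function(estimate, se, covariate,
                                weights = c("inverse_variance",
                                            "inverse_se")) {
  weights <- match.arg(weights)
  n <- length(estimate)
  if (n < 3L) stop("meta-regression needs at least 3 cohorts", call. = FALSE)
  stopifnot(length(se) == n, length(covariate) == n)
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("all standard errors must be positive", call. = FALSE)
  }
  if (length(unique(covariate)) < 2L) {
    stop("covariate values are all equal; slope is unidentified",
         call. = FALSE)
  }
  w <- if (weights == "inverse_variance") 1 / se^2 else 1 / se
  X <- cbind(intercept = 1, covariate = covariate)
  A <- crossprod(X, X * w)          # X'WX
  Ainv <- solve(A)
  b <- Ainv %*% crossprod(X, w * estimate)
  mid <- crossprod(X, X * (w^2 * se^2))  # X'W V W X
  V <- Ainv %*% mid %*% Ainv
  fitted <- drop(X %*% b)
  z <- stats::qnorm(0.975)
  slope <- b[2L]
  slope_se <- sqrt(V[2L, 2L])
  structure(list(
    slope = slope,
    intercept = b[1L],
    slope_se = slope_se,
    intercept_se = sqrt(V[1L, 1L]),
    slope_ci95 = c(lower = slope - z * slope_se,
                   upper = slope + z * slope_se),
    weights_used = weights,
    residuals = estimate - fitted,
    fitted = fitted,
    n = n
  ), class = "meta_regression_fit")
}

#' @export
print.meta_regression_fit <- function(x, ...) {
  cat(sprintf(
    "<meta_regression_fit> %d cohorts, %s weights\n  slope = %.5g (SE %.3g, 95%% CI %.5g to %.5g)\n  intercept = %.5g (SE %.3g)\n",
    x$n, x$weights_used, x$slope, x$slope_se,
    x$slope_ci95[1], x$slope_ci95[2], x$intercept, x$intercept_se))
  invisible(x)
}

#' Mean and standard error of a vector of scores
#'
#' Sample-SD-based standard error of the mean, used to feed per-cohort
#' cluster-score summaries into the meta-regression.
#'
#' @param scores Numeric vector of length >= 2.
#' @return Named numeric vector `c(mean, se)`.
#' @export
standard_error_of_mean <- function(scores) {
  if (length(scores) < 2L) {
    stop("need at least 2 observations for a standard error", call. = FALSE)
  }
  c(mean = mean(scores),
    se = stats::sd(scores) / sqrt(length(scores)))
}
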