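# GWAS design calculations.  All tests are 1-df chi-square; power is the
# upper-tail probability of the noncentral chi-square beyond the central
# upper-alpha quantile.

power_result <- function(ncp, alpha) {
  stopifnot(ncp >= 0, alpha > 0, alpha < 1)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  structure(
    list(power = stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE),
         ncp = ncp, critical_value = crit, alpha = alpha),
    class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("<power_result> power = %.4f (ncp = %.3f, 1-df chi-square, alpha = %g)\n",
              x$power, x$ncp, x$alpha))
  invisible(x)
}

#' Power to detect a quantitative-trait variant
#'
#' Power of the 1-df association test for a variant explaining a given
#' fraction of trait variance, with noncentrality
#' `ncp = n * q / (1 - q)` where `q` is the variance fraction (exact for
#' the chi-square limit of the marginal test; at GWAS-scale effects the
#' difference from `n * q` is negligible, but the convention is fixed).
#'
#' @param n Sample size.
#' @param variance_explained_pct Percent of trait variance explained by
#'   the variant, in (0, 100).
#' @param alpha Significance threshold; defaults to genome-wide 5e-8.
#' @return A `power_result` (fields `power`, `ncp`, `critical_value`).
#' @export
quantitative_power <- function(n, variance_explained_pct, alpha = 5e-8) {
  stopifnot(n > 0, variance_explained_pct >= 0,
            variance_explained_pct < 100)
  q <- variance_explained_pct / 100
  power_result(ncp = n * q / (1 - q), alpha = alpha)
}

#' Minimal detectable variance explained
#'
#' The smallest per-variant fraction of trait variance (in percent)
#' detectable with at least `target_power` at significance `alpha` in a
#' sample of size `n`, solved by monotone root-finding on the log scale
#' to relative tolerance 1e-8.
#'
#' @param n Sample size.
#' @param alpha Significance threshold (default genome-wide 5e-8).
#' @param target_power Required power, in (alpha, 1).
#' @return Percent of variance explained (numeric scalar).
#' @export
min_detectable_var_explained <- function(n, alpha = 5e-8,
                                         target_power = 0.80) {
  stopifnot(n > 0, alpha > 0, alpha < 1,
            target_power > 0, target_power < 1)
  if (target_power <= alpha) {
    stop("target_power must exceed alpha (power at zero effect is alpha)",
         call. = FALSE)
  }
  f <- function(logq) {
    q <- exp(logq)
    power_result(n * q / (1 - q), alpha)$power - target_power
  }
  lo <- log(1e-14)
  hi <- log(1 - 1e-12)
  if (f(hi) < 0) stop("target power unreachable at this n/alpha",
                      call. = FALSE)
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  100 * exp(root)
}

#' Power to detect a binary-trait (case/control) variant
#'
#' Per-allele trend (score) test approximation under Hardy-Weinberg
#' equilibrium: `ncp = (ln OR)^2 * 2 * maf * (1 - maf) *
#' n_cases * n_controls / (n_cases + n_controls)`.
#'
#' @param n_cases,n_controls Case and control counts.
#' @param maf Minor allele frequency in (0, 0.5].
#' @param odds_ratio Per-allele odds ratio (> 0).
#' @param alpha Significance threshold (default genome-wide 5e-8).
#' @return A `power_result`.
#' @export
binary_power <- function(n_cases, n_controls, maf, odds_ratio,
                         alpha = 5e-8) {
  stopifnot(n_cases > 0, n_controls > 0, maf > 0, maf <= 0.5,
            odds_ratio > 0)
  ncp <- log(odds_ratio)^2 * 2 * maf * (1 - maf) *
    n_cases * n_controls / (n_cases + n_controls)
  power_result(ncp = ncp, alpha = alpha)
}

#' Power over a grid of allele frequencies and effect sizes
#'
#' Evaluates the matching power function on the cartesian product of
#' `maf` and `effect` values, suitable for plotting power curves across
#' the allele-frequency spectrum.
#'
#' For `trait = "quantitative"`, `effect` is the per-allele effect in
#' trait-SD units (beta); the implied variance fraction is
#' `beta^2 * 2 * maf * (1 - maf)`.  For `trait = "binary"`, `effect` is
#' the per-allele odds ratio and `n_cases`/`n_controls` are required.
#'
#' @param maf Numeric vector of minor allele frequencies.
#' @param effect Numeric vector of effect sizes (beta in SD units, or OR).
#' @param n Total sample size (quantitative traits).
#' @param n_cases,n_controls Case/control counts (binary traits).
#' @param alpha Significance threshold.
#' @param trait `"quantitative"` or `"binary"`.
#' @return Data frame `maf, effect, power`.
#' @export
power_grid <- function(maf, effect, n = NULL, n_cases = NULL,
                       n_controls = NULL, alpha = 5e-8,
                       trait = c("quantitative", "binary")) {
  trait <- match.arg(trait)
  stopifnot(length(maf) >= 1, length(effect) >= 1)
  g <- expand.grid(maf = maf, effect = effect, KEEP.OUT.ATTRS = FALSE)
  g$power <- vapply(seq_len(nrow(g)), function(i) {
    if (trait == "quantitative") {
      stopifnot(!is.null(n))
      q <- g$effect[i]^2 * 2 * g$maf[i] * (1 - g$maf[i])
      if (q >= 1) return(1)
      quantitative_power(n, 100 * q, alpha)$power
    } else {
      stopifnot(!is.null(n_cases), !is.null(n_controls))
      binary_power(n_cases, n_controls, g$maf[i], g$effect[i], alpha)$power
    }
  }, numeric(1))
  g
}
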