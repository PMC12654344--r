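#' Wald ratio estimate from a single variant
#'
#' `beta_outcome / beta_exposure` with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|`.
#'
#' @param pairs One-row harmonized tibble (see [harmonize()]).
#' @return One-row estimate tibble (`method`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`, `n_snp`).
#' @export
mr_wald <- function(pairs) {
  check_harmonized(pairs, min_snp = 1L, caller = "mr_wald")
  check_that(nrow(pairs) == 1L, "mr_wald takes exactly one SNP")
  check_that(pairs$beta_exposure != 0, "beta_exposure must be nonzero")
  beta <- pairs$beta_outcome / pairs$beta_exposure
  se <- pairs$se_outcome / abs(pairs$beta_exposure)
  estimate_row("wald", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' The primary two-sample MR estimator: a weighted regression of outcome
#' on exposure effects through the origin with weights
#' \eqn{w_j = 1/se_{y,j}^2}, i.e.
#' \eqn{\hat\beta = \sum w_j \beta_{x,j}\beta_{y,j} / \sum w_j \beta_{x,j}^2}.
#' The default multiplicative random-effects variant inflates (never
#' deflates) the standard error by \eqn{\max(1, \sqrt{Q/(n-1)})}, where Q
#' is Cochran's heterogeneity statistic at the fitted slope. A single SNP
#' delegates to [mr_wald()].
#'
#' @param pairs Harmonized tibble with >= 1 SNP.
#' @param variant `"multiplicative_random"` (default) or `"fixed"`.
#' @return One-row estimate tibble with attribute `"q"` carrying the
#'   heterogeneity statistic used for the scaling.
#' @export
mr_ivw <- function(pairs, variant = c("multiplicative_random", "fixed")) {
  variant <- match.arg(variant)
  check_harmonized(pairs, min_snp = 1L, caller = "mr_ivw")
  if (nrow(pairs) == 1L) {
    return(mr_wald(pairs))
  }
  w <- 1 / pairs$se_outcome^2
  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  denom <- sum(w * bx^2)
  beta <- sum(w * bx * by) / denom
  se <- sqrt(1 / denom)
  q <- sum(w * (by - beta * bx)^2)
  if (variant == "multiplicative_random") {
    se <- se * max(1, sqrt(q / (nrow(pairs) - 1)))
  }
  out <- estimate_row("ivw", beta, se, nrow(pairs))
  attr(out, "q") <- q
  out
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome on exposure effects *with* an
#' intercept, weights \eqn{1/se_{y,j}^2}, after re-orienting each SNP so
#' that its exposure effect is nonnegative. The slope is the
#' pleiotropy-robust causal estimate; a nonzero intercept indicates
#' directional pleiotropy. Standard errors use the multiplicative
#' random-effects convention (residual scale floored at 1).
#'
#' @param pairs Harmonized tibble with >= 3 SNPs.
#' @return Two-row estimate tibble, methods `"egger"` (slope) and
#'   `"egger_intercept"`.
#' @export
mr_egger <- function(pairs) {
  check_harmonized(pairs, min_snp = 3L, caller = "mr_egger")
  flip <- ifelse(pairs$beta_exposure < 0, -1, 1)
  bx <- flip * pairs$beta_exposure
  by <- flip * pairs$beta_outcome
  w <- 1 / pairs$se_outcome^2
  n <- nrow(pairs)

  x <- cbind(intercept = 1, slope = bx)
  a <- crossprod(x, w * x)
  b <- crossprod(x, w * by)
  coefs <- drop(solve(a, b))
  resid <- by - drop(x %*% coefs)
  sigma2 <- sum(w * resid^2) / (n - 2)
  vc <- solve(a) * max(1, sigma2)
  ses <- sqrt(diag(vc))

  dplyr::bind_rows(
    estimate_row("egger", coefs[["slope"]], ses[["slope"]], n),
    estimate_row("egger_intercept", coefs[["intercept"]], ses[["intercept"]], n)
  )
}

# per-SNP ratio estimates and their inverse-variance weights
ratio_estimates <- function(pairs) {
  zero <- pairs$beta_exposure == 0
  if (any(zero)) {
    rlang::inform(sprintf(
      "excluded %d SNP(s) with beta_exposure = 0 from ratio-based estimator",
      sum(zero)
    ))
    pairs <- pairs[!zero, , drop = FALSE]
  }
  tibble::tibble(
    snp = pairs$snp,
    ratio = pairs$beta_outcome / pairs$beta_exposure,
    # first-order delta-method variance of the ratio
    weight = pairs$beta_exposure^2 / pairs$se_outcome^2
  )
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord] / sum(weight)
  p <- cumsum(w) - w / 2
  if (p[1] >= 0.5) {
    return(r[1])
  }
  k <- max(which(p < 0.5))
  if (k == length(r)) {
    return(r[length(r)])
  }
  r[k] + (r[k + 1] - r[k]) * (0.5 - p[k]) / (p[k + 1] - p[k])
}

#' Weighted-median estimate
#'
#' The weight-interpolated 50th percentile of the per-SNP ratio estimates,
#' consistent when at least half the instrument weight comes from valid
#' SNPs. Weights are the inverse first-order variances of the ratios. The
#' standard error comes from bootstrap resampling of SNPs.
#'
#' @param pairs Harmonized tibble with >= 3 SNPs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate tibble, method `"weighted_median"`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  check_harmonized(pairs, min_snp = 3L, caller = "mr_weighted_median")
  re <- ratio_estimates(pairs)
  check_that(nrow(re) >= 3, "weighted median requires >= 3 usable SNPs")
  beta <- weighted_median_point(re$ratio, re$weight)
  se <- bootstrap_se(re, weighted_median_point, n_boot, seed)
  estimate_row("weighted_median", beta, se, nrow(re))
}

#' Simple mode-based estimate
#'
#' Smooths the per-SNP ratio estimates with a normal kernel (bandwidth =
#' `bandwidth_factor` times the Silverman plug-in rule on the ratios) and
#' returns the density argmax — the causal effect suggested by the largest
#' cluster of agreeing instruments. Standard error by bootstrap.
#'
#' @param pairs Harmonized tibble with >= 3 SNPs.
#' @param bandwidth_factor Multiplier on the plug-in bandwidth
#'   (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return One-row estimate tibble, method `"mode"`.
#' @export
mr_mode <- function(pairs, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  check_harmonized(pairs, min_snp = 3L, caller = "mr_mode")
  check_config(is_single_number(bandwidth_factor) && bandwidth_factor > 0,
               "`bandwidth_factor` must be a positive number")
  re <- ratio_estimates(pairs)
  check_that(nrow(re) >= 3, "mode estimator requires >= 3 usable SNPs")
  point <- function(ratio, weight) mode_point(ratio, bandwidth_factor)
  beta <- point(re$ratio, re$weight)
  se <- bootstrap_se(re, point, n_boot, seed)
  estimate_row("mode", beta, se, nrow(re))
}

mode_point <- function(ratio, bandwidth_factor) {
  if (diff(range(ratio)) == 0) {
    return(ratio[1])
  }
  bw <- bandwidth_factor * stats::bw.nrd0(ratio)
  d <- stats::density(ratio, bw = bw, n = 1024)
  d$x[which.max(d$y)]
}

bootstrap_se <- function(re, point_fun, n_boot, seed) {
  check_config(is_single_number(seed), "`seed` must be a single integer")
  n <- nrow(re)
  with_seed(as.integer(seed), {
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      point_fun(re$ratio[idx], re$weight[idx])
    }, numeric(1))
    stats::sd(boots)
  })
}
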