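#' Cochran's Q heterogeneity statistic
#'
#' \eqn{Q = \sum_j w_j (\beta_{y,j} - \beta_{ref}\,\beta_{x,j})^2} with
#' \eqn{w_j = 1/se_{y,j}^2}; under homogeneity Q follows a chi-square
#' distribution on `n_snp - 1` degrees of freedom. Excess heterogeneity
#' suggests some instruments act on the outcome through pathways other
#' than the exposure.
#'
#' @param pairs Harmonized tibble with >= 2 SNPs.
#' @param beta_ref Reference causal slope (typically the IVW estimate;
#'   defaults to the fixed-effect IVW slope of `pairs`).
#' @return One-row tibble with `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(pairs, beta_ref = NULL) {
  check_harmonized(pairs, min_snp = 2L, caller = "cochran_q")
  if (is.null(beta_ref)) {
    beta_ref <- mr_ivw(pairs, variant = "fixed")$beta
  }
  check_config(is_single_number(beta_ref), "`beta_ref` must be a single number")
  w <- 1 / pairs$se_outcome^2
  q <- sum(w * (pairs$beta_outcome - beta_ref * pairs$beta_exposure)^2)
  df <- nrow(pairs) - 1L
  tibble::tibble(
    q = q,
    df = df,
    pvalue = stats::pchisq(q, df, lower.tail = FALSE)
  )
}

#' MR-PRESSO global and outlier test
#'
#' Detects pleiotropic outlier instruments by comparing the observed
#' residual sum of squares from leave-one-out IVW fits against a null
#' distribution obtained by parametric simulation: for each draw, exposure
#' and outcome effects are resampled around their fitted values at the
#' observed standard errors, and the same leave-one-out statistic is
#' recomputed. Per-SNP outlier p-values are Bonferroni-corrected over the
#' number of instruments; when outliers are found the IVW estimate is
#' recomputed on the outlier-free set.
#'
#' @param pairs Harmonized tibble with >= 4 SNPs (the leave-one-out
#'   statistic needs at least 3 SNPs per fit).
#' @param n_sim Parametric simulations for the null (default 1000; the
#'   smallest achievable outlier p is `1/(n_sim + 1)`, so `n_sim` must be
#'   large enough for Bonferroni-corrected detection).
#' @param seed Integer seed.
#' @param outlier_alpha Family-wise level for outlier flagging
#'   (default 0.05).
#' @return An object of class `mr_presso`: a list with
#'   `global_pvalue`, `rss_obs`, `outliers` (SNP ids),
#'   `outlier_tests` (per-SNP tibble), `corrected` (IVW estimate row on
#'   the outlier-free set, or `NULL`), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  check_harmonized(pairs, min_snp = 1L, caller = "mr_presso")
  if (nrow(pairs) < 4L) {
    rlang::abort(
      "mr_presso requires at least 4 SNPs so each leave-one-out fit retains 3",
      class = "mrpath_validation_error"
    )
  }
  check_config(is_single_number(n_sim) && n_sim >= 1, "`n_sim` must be >= 1")
  check_config(is_single_number(seed), "`seed` must be a single integer")

  bx <- pairs$beta_exposure
  by <- pairs$beta_outcome
  sx <- pairs$se_exposure
  sy <- pairs$se_outcome
  w <- 1 / sy^2
  n <- length(bx)

  loo_stats <- function(bx, by) {
    num <- sum(w * bx * by)
    den <- sum(w * bx^2)
    beta_loo <- (num - w * bx * by) / (den - w * bx^2)
    d <- w * (by - beta_loo * bx)^2
    list(beta_loo = beta_loo, d = d, rss = sum(d))
  }
  obs <- loo_stats(bx, by)

  sims <- with_seed(as.integer(seed), {
    mu_y <- obs$beta_loo * bx # fitted outcome means under the LOO model
    bx_star <- matrix(stats::rnorm(n_sim * n, rep(bx, each = n_sim),
                                   rep(sx, each = n_sim)), nrow = n_sim)
    by_star <- matrix(stats::rnorm(n_sim * n, rep(mu_y, each = n_sim),
                                   rep(sy, each = n_sim)), nrow = n_sim)
    wm <- matrix(w, nrow = n_sim, ncol = n, byrow = TRUE)
    num_s <- rowSums(wm * bx_star * by_star)
    den_s <- rowSums(wm * bx_star^2)
    beta_loo_s <- (num_s - wm * bx_star * by_star) / (den_s - wm * bx_star^2)
    d_s <- wm * (by_star - beta_loo_s * bx_star)^2
    list(d = d_s, rss = rowSums(d_s))
  })

  global_p <- (1 + sum(sims$rss >= obs$rss)) / (n_sim + 1)
  outlier_p <- vapply(seq_len(n), function(j) {
    (1 + sum(sims$d[, j] >= obs$d[j])) / (n_sim + 1)
  }, numeric(1))
  flagged <- outlier_p * n < outlier_alpha

  outlier_tests <- tibble::tibble(
    snp = pairs$snp,
    d_obs = obs$d,
    pvalue = outlier_p,
    pvalue_bonferroni = pmin(outlier_p * n, 1),
    outlier = flagged
  )

  corrected <- NULL
  if (any(flagged) && sum(!flagged) >= 2) {
    corrected <- mr_ivw(pairs[!flagged, , drop = FALSE])
    corrected$method <- "presso_corrected"
  }

  structure(
    list(
      global_pvalue = global_p,
      rss_obs = obs$rss,
      outliers = pairs$snp[flagged],
      outlier_tests = outlier_tests,
      corrected = corrected,
      n_sim = n_sim,
      seed = as.integer(seed)
    ),
    class = "mr_presso"
  )
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO global test: RSS =", format(x$rss_obs, digits = 4),
      ", p =", format(x$global_pvalue, digits = 4), "\n")
  if (length(x$outliers) > 0) {
    cat("Outliers:", paste(x$outliers, collapse = ", "), "\n")
    if (!is.null(x$corrected)) {
      cat("Outlier-corrected IVW beta:",
          format(x$corrected$beta, digits = 4), "\n")
    }
  } else {
    cat("No outlier instruments detected\n")
  }
  invisible(x)
}
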