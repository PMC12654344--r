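#' Build a meta-analysis study table from odds ratios and 95% CIs
#'
#' Log-transforms each study's odds ratio and recovers its standard error
#' from the printed confidence limits,
#' \eqn{se = (\ln CI_{high} - \ln CI_{low}) / (2 \times 1.959964)}
#' (the z-quantile used by published meta-analysis software, not the
#' rounded 1.96).
#'
#' @param studies Data frame with columns `label`, `or`, `ci_low`,
#'   `ci_high` (or the TSV header `LABEL, OR, CI_LOW, CI_HIGH`).
#' @return A tibble with `label`, `or`, `ci_low`, `ci_high`, `log_or`,
#'   `se`.
#' @export
meta_studies <- function(studies) {
  s <- tibble::as_tibble(studies)
  if (all(c("LABEL", "OR", "CI_LOW", "CI_HIGH") %in% names(s))) {
    s <- dplyr::rename(s, label = "LABEL", or = "OR",
                       ci_low = "CI_LOW", ci_high = "CI_HIGH")
  }
  check_config(
    all(c("label", "or", "ci_low", "ci_high") %in% names(s)),
    "study table needs columns label/or/ci_low/ci_high"
  )
  check_that(s$or > 0 & s$ci_low > 0 & s$ci_high > 0,
             "odds ratios and CI bounds must be strictly positive")
  check_that(s$ci_low <= s$or & s$or <= s$ci_high,
             "each odds ratio must lie inside its CI")
  check_that(s$ci_high > s$ci_low, "ci_high must exceed ci_low")
  s |>
    dplyr::mutate(
      log_or = log(.data$or),
      se = (log(.data$ci_high) - log(.data$ci_low)) / (2 * Z95)
    )
}

#' Read a meta-analysis study table from TSV
#'
#' @param path TSV with header `LABEL, OR, CI_LOW, CI_HIGH`.
#' @return See [meta_studies()].
#' @export
read_meta_studies <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  meta_studies(raw)
}

# DerSimonian-Laird moment estimator of between-study variance
tau2_dl <- function(y, se) {
  w <- 1 / se^2
  mu_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - mu_fe)^2)
  df <- length(y) - 1
  max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
}

# restricted maximum-likelihood estimator, profiled over tau2
tau2_reml <- function(y, se) {
  nll <- function(tau2) {
    v <- se^2 + tau2
    w <- 1 / v
    mu <- sum(w * y) / sum(w)
    0.5 * (sum(log(v)) + log(sum(w)) + sum(w * (y - mu)^2))
  }
  upper <- max(stats::var(y) * 4, max(se^2) * 4, 1e-3)
  opt <- stats::optimize(nll, c(0, upper), tol = 1e-12)
  if (nll(0) <= opt$objective) 0 else opt$minimum
}

#' Random-effects meta-analysis of odds ratios
#'
#' Pools log odds ratios with inverse-variance weights
#' \eqn{1/(se_i^2 + \tau^2)}, accounting for both within-study error and
#' between-study heterogeneity. Heterogeneity is summarised by the
#' fixed-effect Cochran Q, its p-value, and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}. The between-study variance
#' \eqn{\tau^2} is estimated by restricted maximum likelihood (default)
#' or the DerSimonian-Laird moment formula
#' \eqn{\max(0, (Q - df)/(\sum w - \sum w^2 / \sum w))}.
#'
#' @param studies Study table from [meta_studies()] (columns `log_or`,
#'   `se`; built on the fly if `or`/`ci_low`/`ci_high` are present
#'   instead).
#' @param tau2_method `"REML"` (default) or `"DL"`.
#' @return An object of class `meta_result`: list with `studies`
#'   (including fixed and normalized random weights), `pooled_log_or`,
#'   `pooled_se`, `pooled_or`, `ci_low`, `ci_high`, `pvalue`, `tau2`,
#'   `tau2_method`, `q`, `q_df`, `q_pvalue`, `i2` (percent), `n_studies`.
#' @examples
#' studies <- tibble::tibble(
#'   label = c("A", "B"),
#'   or = c(1.2, 1.3), ci_low = c(1.0, 1.1), ci_high = c(1.44, 1.54)
#' )
#' pool_random_effects(studies)
#' @export
pool_random_effects <- function(studies, tau2_method = c("REML", "DL")) {
  tau2_method <- match.arg(tau2_method)
  s <- if (!all(c("log_or", "se") %in% names(studies))) {
    meta_studies(studies)
  } else {
    tibble::as_tibble(studies)
  }
  check_that(s$se > 0, "study standard errors must be > 0")
  k <- nrow(s)
  check_that(k >= 1, "at least one study required")

  y <- s$log_or
  se <- s$se
  w <- 1 / se^2

  if (k == 1) {
    rlang::warn("single study: pooled estimate is a pass-through, tau2 = 0")
    tau2 <- 0
    q <- 0
    df <- 0L
    q_p <- 1
    i2 <- 0
  } else {
    mu_fe <- sum(w * y) / sum(w)
    q <- sum(w * (y - mu_fe)^2)
    df <- k - 1L
    q_p <- stats::pchisq(q, df, lower.tail = FALSE)
    i2 <- max(0, (q - df) / q) * 100
    tau2 <- switch(tau2_method, DL = tau2_dl(y, se), REML = tau2_reml(y, se))
  }

  wr <- 1 / (se^2 + tau2)
  mu <- sum(wr * y) / sum(wr)
  se_mu <- sqrt(1 / sum(wr))

  s$weight_fixed <- w / sum(w)
  s$weight_random <- wr / sum(wr)

  structure(
    list(
      studies = s,
      pooled_log_or = mu,
      pooled_se = se_mu,
      pooled_or = exp(mu),
      ci_low = exp(mu - Z95 * se_mu),
      ci_high = exp(mu + Z95 * se_mu),
      pvalue = two_sided_p(mu / se_mu),
      tau2 = tau2,
      tau2_method = tau2_method,
      q = q,
      q_df = df,
      q_pvalue = q_p,
      i2 = i2,
      n_studies = k
    ),
    class = "meta_result"
  )
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Random-effects meta-analysis (%d studies, tau2 %s = %.5f)\n",
    x$n_studies, x$tau2_method, x$tau2
  ))
  cat(sprintf("Pooled OR = %.4f (95%% CI %.4f-%.4f), p = %.4g\n",
              x$pooled_or, x$ci_low, x$ci_high, x$pvalue))
  cat(sprintf("Heterogeneity: Q = %.3f (df %d, p = %.4g), I2 = %.1f%%\n",
              x$q, x$q_df, x$q_pvalue, x$i2))
  invisible(x)
}

#' @rdname pool_random_effects
#' @param x A `meta_result`.
#' @param ... Unused.
#' @return `tidy()`: a forest-plot table — one row per study plus a
#'   pooled row, with OR, CI bounds and normalized random-effects
#'   weights.
#' @method tidy meta_result
#' @export
tidy.meta_result <- function(x, ...) {
  per_study <- tibble::tibble(
    label = x$studies$label,
    or = x$studies$or,
    ci_low = x$studies$ci_low,
    ci_high = x$studies$ci_high,
    weight_fixed = x$studies$weight_fixed,
    weight_random = x$studies$weight_random,
    pooled = FALSE
  )
  pooled <- tibble::tibble(
    label = "Pooled (random effects)",
    or = x$pooled_or,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    weight_fixed = NA_real_,
    weight_random = NA_real_,
    pooled = TRUE
  )
  dplyr::bind_rows(per_study, pooled)
}

#' @rdname pool_random_effects
#' @method glance meta_result
#' @export
glance.meta_result <- function(x, ...) {
  tibble::tibble(
    n_studies = x$n_studies,
    pooled_or = x$pooled_or,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    pvalue = x$pvalue,
    tau2 = x$tau2,
    tau2_method = x$tau2_method,
    q = x$q,
    q_df = x$q_df,
    q_pvalue = x$q_pvalue,
    i2 = x$i2
  )
}
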