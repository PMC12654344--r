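#' Two-step mediation decomposition
#'
#' Decomposes a total exposure-outcome effect into the component carried
#' through a mediator and the remainder: the indirect effect is the
#' product of coefficients \eqn{\beta_1 \beta_2}
#' (exposure-to-mediator times mediator-to-outcome), the direct effect is
#' \eqn{\beta_{all} - \beta_1\beta_2}, and the proportion mediated is
#' \eqn{(\beta_1\beta_2)/\beta_{all}}, reported as a percentage of
#' magnitude `|indirect/total| * 100` together with a sign-consistency
#' flag (an indirect effect opposing the total marks "inconsistent
#' mediation"). The proportion's standard error comes from the delta
#' method on the product and ratio, treating the three estimates as
#' independent (they come from non-overlapping instrument sets); its 95%
#' interval is truncated to \[0, 100\]%.
#'
#' All arguments are vectorized; standard errors may be `NA` when only
#' the point decomposition is needed.
#'
#' @param beta_total Total exposure-outcome effect (\eqn{\beta_{all}}).
#' @param beta1 Exposure-mediator effect.
#' @param beta2 Mediator-outcome effect.
#' @param se_total,se1,se2 Standard errors (> 0, or `NA` to skip
#'   uncertainty propagation).
#' @return A tibble with the input coefficients, `indirect`,
#'   `se_indirect`, `direct`, `proportion` (percent), `se_proportion`,
#'   `proportion_ci_low`, `proportion_ci_high`, `sign_consistent` and
#'   `proportion_defined` (`FALSE` when `beta_total` is 0).
#' @export
decompose <- function(beta_total, beta1, beta2,
                      se_total = NA_real_, se1 = NA_real_, se2 = NA_real_) {
  check_that(is.na(se_total) | se_total > 0, "`se_total` must be > 0")
  check_that(is.na(se1) | se1 > 0, "`se1` must be > 0")
  check_that(is.na(se2) | se2 > 0, "`se2` must be > 0")

  indirect <- beta1 * beta2
  direct <- beta_total - indirect
  se_indirect <- sqrt(beta2^2 * se1^2 + beta1^2 * se2^2)

  defined <- beta_total != 0
  if (any(!defined)) {
    rlang::warn("beta_total = 0: proportion mediated undefined for some rows")
  }
  ratio <- ifelse(defined, indirect / beta_total, NA_real_)
  # delta method on indirect/total, independent numerator and denominator
  se_ratio <- ifelse(
    defined,
    sqrt(se_indirect^2 + ratio^2 * se_total^2) / abs(beta_total),
    NA_real_
  )
  proportion <- abs(ratio) * 100
  se_proportion <- se_ratio * 100
  ci_low <- pmax(proportion - Z95 * se_proportion, 0)
  ci_high <- pmin(proportion + Z95 * se_proportion, 100)

  tibble::tibble(
    beta_total = beta_total, se_total = se_total,
    beta1 = beta1, se1 = se1,
    beta2 = beta2, se2 = se2,
    indirect = indirect, se_indirect = se_indirect,
    direct = direct,
    proportion = proportion, se_proportion = se_proportion,
    proportion_ci_low = ci_low, proportion_ci_high = ci_high,
    sign_consistent = !defined | indirect == 0 |
      sign(indirect) == sign(beta_total),
    proportion_defined = defined
  )
}

#' Two-step MR mediation from three estimator batteries
#'
#' Takes the IVW estimates of three links — exposure to mediator
#' (\eqn{\beta_1}), mediator to outcome (\eqn{\beta_2}) and exposure to
#' outcome (\eqn{\beta_{all}}) — and applies [decompose()]. Mediation is
#' attempted only when the step-1 and step-2 links both pass the
#' [run_battery()] reliability rule; otherwise the decomposition is
#' returned with the proportion blanked and `eligible = FALSE`, so the
#' flags record exactly which link failed.
#'
#' @param step1 `mr_battery` for exposure -> mediator.
#' @param step2 `mr_battery` for mediator -> outcome.
#' @param total `mr_battery` for exposure -> outcome.
#' @return A one-row tibble: the [decompose()] columns plus
#'   `step1_reliable`, `step2_reliable`, `total_reliable`, `eligible`.
#' @export
two_step <- function(step1, step2, total) {
  for (nm in c("step1", "step2", "total")) {
    b <- get(nm)
    check_config(inherits(b, "mr_battery"),
                 paste0("`", nm, "` must be an mr_battery object"))
  }
  ivw_of <- function(b) b$estimates[b$estimates$method %in% c("ivw", "wald"), ][1, ]
  e1 <- ivw_of(step1)
  e2 <- ivw_of(step2)
  et <- ivw_of(total)

  res <- decompose(
    beta_total = et$beta, beta1 = e1$beta, beta2 = e2$beta,
    se_total = et$se, se1 = e1$se, se2 = e2$se
  )
  eligible <- step1$reliable && step2$reliable
  if (!eligible) {
    res$proportion <- NA_real_
    res$se_proportion <- NA_real_
    res$proportion_ci_low <- NA_real_
    res$proportion_ci_high <- NA_real_
  }
  res$step1_reliable <- step1$reliable
  res$step2_reliable <- step2$reliable
  res$total_reliable <- total$reliable
  res$eligible <- eligible
  res
}
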