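#' Run the full MR estimator battery with sensitivity analyses
#'
#' Computes IVW (the primary estimator), weighted-median, MR-Egger and
#' mode-based estimates plus Cochran's Q, the Egger intercept and
#' MR-PRESSO, then applies the cross-method reliability rule: an
#' exposure-outcome link is called *reliable* only when the IVW p-value is
#' below `alpha` **and** the sign of the causal estimate agrees across
#' IVW, weighted median, the Egger slope, and the PRESSO outlier-corrected
#' estimate when one is produced. With fewer than 3 (or 4, for PRESSO)
#' SNPs the battery degrades to the estimators the set supports and says
#' so.
#'
#' @param pairs Harmonized tibble (see [harmonize()]).
#' @param alpha Significance level for the IVW gate (default 0.05).
#' @param ivw_variant Passed to [mr_ivw()].
#' @param methods Ratio estimators to run alongside IVW; any subset of
#'   `c("weighted_median", "egger", "mode")`.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param presso_sims Simulations for [mr_presso()].
#' @param include_presso Run MR-PRESSO when >= 4 SNPs (default TRUE).
#' @param seed Integer seed governing all stochastic components.
#' @param exposure_name,outcome_name Optional labels carried in the report.
#' @return An object of class `mr_battery`: list with `estimates` (tidy
#'   tibble, one row per method), `q` (Cochran's Q row at the IVW slope),
#'   `presso` ([mr_presso()] result or `NULL`), `reliable` (logical
#'   verdict), `signs_agree`, `degraded`, `alpha`, `n_snp`, labels.
#' @export
run_battery <- function(pairs,
                        alpha = 0.05,
                        ivw_variant = c("multiplicative_random", "fixed"),
                        methods = c("weighted_median", "egger", "mode"),
                        n_boot = 1000,
                        presso_sims = 1000,
                        include_presso = TRUE,
                        seed = 1,
                        exposure_name = "exposure",
                        outcome_name = "outcome") {
  ivw_variant <- match.arg(ivw_variant)
  methods <- match.arg(methods, c("weighted_median", "egger", "mode"),
                       several.ok = TRUE)
  check_harmonized(pairs, min_snp = 1L, caller = "run_battery")
  check_config(is_single_number(alpha) && alpha > 0 && alpha < 1,
               "`alpha` must be in (0, 1)")
  n <- nrow(pairs)

  ivw <- mr_ivw(pairs, variant = ivw_variant)
  est <- list(ivw)
  degraded <- n < 3 || (include_presso && n < 4)

  if (n >= 3) {
    if ("weighted_median" %in% methods) {
      est <- c(est, list(mr_weighted_median(pairs, n_boot = n_boot, seed = seed)))
    }
    if ("egger" %in% methods) {
      est <- c(est, list(mr_egger(pairs)))
    }
    if ("mode" %in% methods) {
      est <- c(est, list(mr_mode(pairs, n_boot = n_boot, seed = seed + 1L)))
    }
  }
  estimates <- dplyr::bind_rows(est)

  q <- if (n >= 2) cochran_q(pairs, beta_ref = ivw$beta) else NULL
  presso <- NULL
  if (include_presso && n >= 4) {
    presso <- mr_presso(pairs, n_sim = presso_sims, seed = seed + 2L)
    if (!is.null(presso$corrected)) {
      estimates <- dplyr::bind_rows(estimates, presso$corrected)
    }
  }

  sign_methods <- intersect(
    c("ivw", "wald", "weighted_median", "egger", "presso_corrected"),
    estimates$method
  )
  signs <- sign(estimates$beta[estimates$method %in% sign_methods])
  signs_agree <- length(unique(signs[signs != 0])) <= 1
  ivw_row <- estimates[estimates$method %in% c("ivw", "wald"), ][1, ]
  reliable <- isTRUE(ivw_row$pvalue < alpha) && signs_agree

  structure(
    list(
      estimates = estimates,
      q = q,
      presso = presso,
      reliable = reliable,
      signs_agree = signs_agree,
      degraded = degraded,
      alpha = alpha,
      n_snp = n,
      exposure_name = exposure_name,
      outcome_name = outcome_name,
      seed = as.integer(seed)
    ),
    class = "mr_battery"
  )
}

#' @export
print.mr_battery <- function(x, ...) {
  cat(sprintf("MR battery: %s -> %s (%d SNP%s)\n",
              x$exposure_name, x$outcome_name, x$n_snp,
              if (x$n_snp == 1) "" else "s"))
  print(x$estimates)
  if (!is.null(x$q)) {
    cat(sprintf("Cochran's Q = %.3f (df %d), p = %.4g\n",
                x$q$q, x$q$df, x$q$pvalue))
  }
  if (!is.null(x$presso)) {
    cat(sprintf("MR-PRESSO global p = %.4g; %d outlier(s)\n",
                x$presso$global_pvalue, length(x$presso$outliers)))
  }
  cat("Verdict:", if (x$reliable) "reliable" else "not reliable",
      if (x$degraded) "(degraded battery)" else "", "\n")
  invisible(x)
}

#' @rdname run_battery
#' @param x An `mr_battery` object.
#' @param ... Unused.
#' @method tidy mr_battery
#' @export
tidy.mr_battery <- function(x, ...) {
  x$estimates
}

#' @rdname run_battery
#' @method glance mr_battery
#' @export
glance.mr_battery <- function(x, ...) {
  ivw_row <- x$estimates[x$estimates$method %in% c("ivw", "wald"), ][1, ]
  egger_int <- x$estimates[x$estimates$method == "egger_intercept", ]
  tibble::tibble(
    exposure = x$exposure_name,
    outcome = x$outcome_name,
    n_snp = x$n_snp,
    ivw_beta = ivw_row$beta,
    ivw_se = ivw_row$se,
    ivw_pvalue = ivw_row$pvalue,
    q = if (is.null(x$q)) NA_real_ else x$q$q,
    q_pvalue = if (is.null(x$q)) NA_real_ else x$q$pvalue,
    egger_intercept = if (nrow(egger_int)) egger_int$beta else NA_real_,
    egger_intercept_pvalue = if (nrow(egger_int)) egger_int$pvalue else NA_real_,
    presso_global_pvalue =
      if (is.null(x$presso)) NA_real_ else x$presso$global_pvalue,
    n_outliers = if (is.null(x$presso)) NA_integer_
                 else length(x$presso$outliers),
    signs_agree = x$signs_agree,
    reliable = x$reliable,
    degraded = x$degraded
  )
}

#' Bidirectional MR
#'
#' Runs the estimator battery in both directions of a putative causal
#' relationship; each direction is prepared (selected, clumped,
#' harmonized) with its own instrument thresholds upstream. An
#' association is flagged `"unidirectional"` when the forward link is
#' reliable while the reverse IVW shows no signal, `"bidirectional"` when
#' both are reliable, and `"none"` otherwise. An empty reverse (or
#' forward) instrument set is reported as `"no instruments"` without
#' affecting the other direction.
#'
#' @param forward,reverse Harmonized instrument tibbles for the two
#'   directions; `NULL` or zero rows mark a direction without instruments.
#' @param ... Passed on to [run_battery()].
#' @return An object of class `mr_bidirectional`: list with `forward`,
#'   `reverse` (each an `mr_battery` or the string `"no instruments"`)
#'   and `interpretation`.
#' @export
bidirectional <- function(forward, reverse, ...) {
  run_dir <- function(pairs, label) {
    if (is.null(pairs) || nrow(pairs) == 0) {
      return("no instruments")
    }
    run_battery(pairs, ...)
  }
  fwd <- run_dir(forward, "forward")
  rev <- run_dir(reverse, "reverse")

  sig <- function(b) {
    if (!inherits(b, "mr_battery")) {
      return(FALSE)
    }
    b$reliable
  }
  interpretation <- if (sig(fwd) && sig(rev)) {
    "bidirectional"
  } else if (sig(fwd)) {
    "unidirectional (forward)"
  } else if (sig(rev)) {
    "unidirectional (reverse)"
  } else {
    "none"
  }

  structure(
    list(forward = fwd, reverse = rev, interpretation = interpretation),
    class = "mr_bidirectional"
  )
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  cat("== Forward direction ==\n")
  if (inherits(x$forward, "mr_battery")) print(x$forward) else cat(x$forward, "\n")
  cat("== Reverse direction ==\n")
  if (inherits(x$reverse, "mr_battery")) print(x$reverse) else cat(x$reverse, "\n")
  cat("Interpretation:", x$interpretation, "\n")
  invisible(x)
}
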