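# internal helpers shared across modules

Z95 <- 1.959964 # two-sided 95% normal quantile, matching published software

# wrap a normal-theory estimate into the common one-row estimate tibble
estimate_row <- function(method, beta, se, n_snp) {
  tibble::tibble(
    method = method,
    beta = beta,
    se = se,
    ci_low = beta - Z95 * se,
    ci_high = beta + Z95 * se,
    pvalue = two_sided_p(beta / se),
    n_snp = as.integer(n_snp)
  )
}

two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(pmin(p, 1), .Machine$double.xmin)
}

# validation guard: `cond` must hold for every element, else abort with class
check_that <- function(cond, msg, class = "mrpath_validation_error") {
  if (!all(cond, na.rm = FALSE) || anyNA(cond)) {
    rlang::abort(msg, class = class)
  }
  invisible(TRUE)
}

check_config <- function(cond, msg) {
  check_that(cond, msg, class = "mrpath_config_error")
}

# run `expr` under a seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}

is_single_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# columns shared by harmonized instrument tables
harmonized_cols <- c(
  "snp", "beta_exposure", "se_exposure", "beta_outcome", "se_outcome"
)

check_harmonized <- function(pairs, min_snp = 1L, caller = "this estimator") {
  check_that(is.data.frame(pairs), "`pairs` must be a data frame of harmonized SNPs")
  missing <- setdiff(harmonized_cols, names(pairs))
  check_config(
    length(missing) == 0,
    paste0("harmonized table lacks column(s): ", paste(missing, collapse = ", "))
  )
  check_that(!anyDuplicated(pairs$snp), "duplicate snp ids in harmonized table")
  check_that(pairs$se_exposure > 0, "se_exposure must be strictly positive")
  check_that(pairs$se_outcome > 0, "se_outcome must be strictly positive")
  if (nrow(pairs) < min_snp) {
    rlang::abort(
      sprintf("%s requires at least %d SNP(s); got %d", caller, min_snp, nrow(pairs)),
      class = "mrpath_validation_error"
    )
  }
  invisible(TRUE)
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
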