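#' Filter summary statistics by association p-value
#'
#' Keeps exactly the records whose p-value is strictly below `threshold`
#' (the conventional instrument-selection tiers are `1e-5` for microbial
#' taxa, `5e-6` for plasma metabolites and the genome-wide `5e-8` for
#' disease outcomes). Input order is preserved.
#'
#' @param stats Summary-statistics tibble.
#' @param threshold Significance level in (0, 1]; strict inequality.
#' @return The subset tibble, in input order.
#' @export
select_by_pvalue <- function(stats, threshold) {
  validate_summary_stats(stats)
  check_config(
    is_single_number(threshold) && threshold > 0 && threshold <= 1,
    "`threshold` must be a single value in (0, 1]"
  )
  out <- dplyr::filter(stats, .data$pvalue < threshold)
  if (nrow(out) == 0) {
    rlang::inform("select_by_pvalue: no records pass the threshold")
  }
  out
}

#' Per-SNP variance in the exposure explained by a variant
#'
#' Computes, from summary statistics alone,
#' \deqn{R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
#'   {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
#'    2\,\mathrm{EAF}(1-\mathrm{EAF})\,\mathrm{SE}^2 N}}
#' the proportion of phenotypic variance explained by one SNP. All
#' arguments are vectorized and recycled.
#'
#' @param eaf Effect-allele frequency in (0, 1).
#' @param beta Per-allele effect estimate.
#' @param se Standard error of `beta` (> 0).
#' @param n GWAS sample size (>= 2).
#' @return Numeric vector of values in \[0, 1).
#' @export
compute_variance_explained <- function(eaf, beta, se, n) {
  check_that(eaf > 0 & eaf < 1, "`eaf` must be strictly inside (0,1)")
  check_that(se > 0, "`se` must be > 0")
  check_that(n >= 2, "`n` must be >= 2")
  num <- 2 * eaf * (1 - eaf) * beta^2
  num / (num + 2 * eaf * (1 - eaf) * se^2 * n)
}

#' Instrument-strength F-statistic
#'
#' \eqn{F = R^2 (N - 2) / (1 - R^2)}; values below 10 conventionally flag
#' weak instruments.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param n GWAS sample size (>= 3).
#' @return Nonnegative numeric vector.
#' @export
compute_f <- function(r2, n) {
  check_that(r2 >= 0 & r2 < 1, "`r2` must be in [0, 1)")
  check_that(n >= 3, "`n` must be >= 3")
  r2 * (n - 2) / (1 - r2)
}

#' Annotate summary statistics with instrument strength
#'
#' Adds `r2` ([compute_variance_explained()]) and `f_statistic`
#' ([compute_f()]) columns, each computed per SNP from that record's own
#' EAF, beta, SE and sample size.
#'
#' @param stats Summary-statistics tibble.
#' @return `stats` with `r2` and `f_statistic` columns appended.
#' @export
add_instrument_strength <- function(stats) {
  validate_summary_stats(stats)
  stats |>
    dplyr::mutate(
      r2 = compute_variance_explained(.data$eaf, .data$beta, .data$se, .data$n),
      f_statistic = compute_f(.data$r2, .data$n)
    )
}

#' Remove weak instruments
#'
#' Drops records with `f_statistic` strictly below `f_min` (the boundary
#' value itself is retained). Strength columns are added if absent.
#'
#' @param stats Summary-statistics tibble.
#' @param f_min Minimum F-statistic (default 10).
#' @return The filtered tibble.
#' @export
filter_weak_instruments <- function(stats, f_min = 10) {
  if (!"f_statistic" %in% names(stats)) {
    stats <- add_instrument_strength(stats)
  }
  removed <- sum(stats$f_statistic < f_min)
  if (removed > 0) {
    rlang::inform(sprintf(
      "filter_weak_instruments: removed %d SNP(s) with F < %g", removed, f_min
    ))
  }
  dplyr::filter(stats, .data$f_statistic >= f_min)
}

#' Read a squared-correlation LD matrix from TSV
#'
#' Expects a square matrix with SNP ids as both header row and first
#' column.
#'
#' @param path TSV file path.
#' @return A symmetric numeric matrix with unit diagonal and SNP-id
#'   dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  ids <- as.character(raw[[1]])
  m <- as.matrix(raw[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, colnames(raw)[-1])
  validate_ld_matrix(m)
  m
}

#' Validate a squared-correlation LD matrix
#'
#' @param ld Square numeric matrix with SNP-id dimnames, entries in
#'   \[0, 1\], symmetric, unit diagonal.
#' @return `ld`, invisibly, if valid.
#' @export
validate_ld_matrix <- function(ld) {
  check_that(is.matrix(ld) && nrow(ld) == ncol(ld), "LD matrix must be square")
  check_that(!is.null(rownames(ld)) && identical(rownames(ld), colnames(ld)),
             "LD matrix must carry identical row/column SNP ids")
  check_that(ld >= 0 & ld <= 1, "LD r2 entries must lie in [0, 1]")
  check_that(abs(ld - t(ld)) < 1e-8, "LD matrix must be symmetric")
  check_that(abs(diag(ld) - 1) < 1e-8, "LD matrix diagonal must be 1")
  invisible(ld)
}

#' Greedy LD clumping
#'
#' Thins correlated variants the way standard GWAS clumping does:
#' repeatedly promote the remaining record with the smallest p-value to
#' index SNP, then discard every other remaining record on the same
#' chromosome within `window_kb` kilobases (inclusive) whose squared
#' correlation with the index is at or above `r2_threshold`. Records on a
#' different chromosome, or outside the window, are never removed by that
#' index regardless of the recorded r2. Ties on p-value break by smaller
#' position, then lexicographic SNP id.
#'
#' @param stats Summary-statistics tibble with `chrom` and `pos` filled.
#' @param ld Squared-correlation matrix covering the SNPs (missing pairs
#'   are treated as r2 = 0).
#' @param r2_threshold Independence threshold (default 0.001).
#' @param window_kb Window half-width in kb around each index SNP
#'   (default 10000).
#' @return The retained index SNPs, in selection (p-value) order.
#' @export
clump <- function(stats, ld, r2_threshold = 0.001, window_kb = 10000) {
  validate_summary_stats(stats)
  check_that(!anyNA(stats$chrom) && !anyNA(stats$pos),
             "clumping requires chrom and pos on every record")
  validate_ld_matrix(ld)
  if (nrow(stats) == 0) {
    return(stats)
  }
  missing_ld <- setdiff(stats$snp, rownames(ld))
  if (length(missing_ld) > 0) {
    rlang::inform(sprintf(
      "clump: %d SNP(s) absent from the LD matrix treated as r2 = 0",
      length(missing_ld)
    ))
  }

  ld_r2 <- function(a, b) {
    if (a %in% rownames(ld) && b %in% rownames(ld)) ld[a, b] else 0
  }
  window_bp <- window_kb * 1000

  remaining <- stats |>
    dplyr::arrange(.data$pvalue, .data$pos, .data$snp)
  keep <- integer(0)
  alive <- rep(TRUE, nrow(remaining))
  for (i in seq_len(nrow(remaining))) {
    if (!alive[i]) next
    keep <- c(keep, i)
    idx <- remaining[i, ]
    for (j in seq_len(nrow(remaining))) {
      if (!alive[j] || j == i) next
      same_chr <- remaining$chrom[j] == idx$chrom
      in_window <- same_chr && abs(remaining$pos[j] - idx$pos) <= window_bp
      if (in_window && ld_r2(idx$snp, remaining$snp[j]) >= r2_threshold) {
        alive[j] <- FALSE
      }
    }
  }
  remaining[keep, ]
}

#' Screen instruments against known confounders
#'
#' Removes any SNP showing an association with a listed confounder trait
#' at `pvalue < threshold` (e.g. obesity, BMI, waist circumference, type 2
#' diabetes, metabolic syndrome, depression, smoking, alcohol, coffee
#' intake), so surviving instruments better satisfy the independence
#' assumption.
#'
#' @param stats Summary-statistics tibble of candidate instruments.
#' @param confounder_assoc Tibble (or TSV-derived data frame) with columns
#'   `snp`, `trait`, `pvalue` (canonical file header `SNP, TRAIT, P`).
#' @param threshold Removal threshold (default 1e-5, strict).
#' @return `stats` without the confounded SNPs; removals are reported with
#'   their trait names.
#' @export
screen_confounders <- function(stats, confounder_assoc, threshold = 1e-5) {
  validate_summary_stats(stats)
  if (is.null(confounder_assoc) || nrow(confounder_assoc) == 0) {
    return(stats)
  }
  ca <- tibble::as_tibble(confounder_assoc)
  if (all(c("SNP", "TRAIT", "P") %in% names(ca))) {
    ca <- dplyr::rename(ca, snp = "SNP", trait = "TRAIT", pvalue = "P")
  }
  check_config(
    all(c("snp", "trait", "pvalue") %in% names(ca)),
    "confounder table needs columns snp/trait/pvalue (or SNP/TRAIT/P)"
  )
  hits <- ca |>
    dplyr::filter(.data$pvalue < threshold, .data$snp %in% stats$snp)
  if (nrow(hits) > 0) {
    msg <- hits |>
      dplyr::group_by(.data$snp) |>
      dplyr::summarise(traits = paste(unique(.data$trait), collapse = ","),
                       .groups = "drop")
    rlang::inform(paste0(
      "screen_confounders: removed ",
      paste(sprintf("%s (%s)", msg$snp, msg$traits), collapse = "; ")
    ))
  }
  dplyr::filter(stats, !.data$snp %in% hits$snp)
}

#' Read a confounder-association table from TSV
#'
#' @param path TSV with columns `SNP`, `TRAIT`, `P`.
#' @return Tibble with columns `snp`, `trait`, `pvalue`.
#' @export
read_confounder_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  check_config(
    all(c("SNP", "TRAIT", "P") %in% names(raw)),
    "confounder table must have columns SNP, TRAIT, P"
  )
  tibble::tibble(
    snp = as.character(raw$SNP),
    trait = as.character(raw$TRAIT),
    pvalue = as.numeric(raw$P)
  )
}
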