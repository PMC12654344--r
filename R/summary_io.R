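#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file (delimiter auto-detected from the
#' header line) of per-SNP association statistics and returns a validated
#' tibble in the package's canonical layout. Binary-trait effects are
#' expected on the log odds-ratio scale.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names to
#'   the file's column names, e.g. `c(snp = "rsid", beta = "Effect", ...)`.
#'   When `NULL` the canonical names `SNP, CHR, POS, EA, OA, EAF, BETA, SE,
#'   P, N` are assumed. When supplied it must resolve every required field
#'   (`snp`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`,
#'   `n`); `chrom` and `pos` are optional.
#'
#' @return A tibble with columns `snp`, `chrom`, `pos`, `effect_allele`,
#'   `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`, one row per SNP in
#'   file order. Duplicate SNP ids are resolved by keeping the row with the
#'   smallest p-value (the discarded rows are reported via a message).
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c(
#'   "SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
#'   "rs1\tA\tG\t0.25\t0.12\t0.02\t1e-9\t10000"
#' ), tf)
#' read_summary_stats(tf)
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  check_config(file.exists(path), paste0("file not found: ", path))
  header <- readLines(path, n = 1L)
  delim <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- readr::read_delim(
    path,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )

  map <- resolve_column_map(column_map)
  required <- setdiff(names(map), c("chrom", "pos"))
  for (field in required) {
    check_config(
      map[[field]] %in% names(raw),
      paste0("required column '", map[[field]], "' (field '", field,
             "') not present in ", path)
    )
  }

  out <- tibble::tibble(
    snp = raw[[map[["snp"]]]],
    chrom = optional_col(raw, map, "chrom"),
    pos = parse_num(optional_col(raw, map, "pos"), "pos", integer = TRUE),
    effect_allele = toupper(raw[[map[["effect_allele"]]]]),
    other_allele = toupper(raw[[map[["other_allele"]]]]),
    eaf = parse_num(raw[[map[["eaf"]]]], "eaf"),
    beta = parse_num(raw[[map[["beta"]]]], "beta"),
    se = parse_num(raw[[map[["se"]]]], "se"),
    pvalue = parse_num(raw[[map[["pvalue"]]]], "pvalue"),
    n = parse_num(raw[[map[["n"]]]], "n", integer = TRUE)
  )
  validate_summary_stats(out)
  dedupe_summary(out)
}

canonical_column_map <- c(
  snp = "SNP", chrom = "CHR", pos = "POS", effect_allele = "EA",
  other_allele = "OA", eaf = "EAF", beta = "BETA", se = "SE",
  pvalue = "P", n = "N"
)

resolve_column_map <- function(column_map) {
  if (is.null(column_map)) {
    return(as.list(canonical_column_map))
  }
  check_config(
    is.character(column_map) && !is.null(names(column_map)),
    "`column_map` must be a named character vector"
  )
  required <- setdiff(names(canonical_column_map), c("chrom", "pos"))
  missing <- setdiff(required, names(column_map))
  check_config(
    length(missing) == 0,
    paste0("`column_map` must resolve required field(s): ",
           paste(missing, collapse = ", "))
  )
  as.list(column_map)
}

optional_col <- function(raw, map, field) {
  nm <- map[[field]]
  if (!is.null(nm) && nm %in% names(raw)) raw[[nm]] else NA_character_
}

parse_num <- function(x, field, integer = FALSE) {
  if (all(is.na(x))) {
    return(if (integer) NA_integer_ else NA_real_)
  }
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    rlang::abort(
      sprintf("column '%s': unparsable numeric value '%s' at row %d",
              field, x[bad[1]], bad[1]),
      class = "mrpath_validation_error"
    )
  }
  if (integer) as.integer(round(out)) else out
}

#' Validate a summary-statistics tibble
#'
#' Checks the per-SNP invariants: single-base distinct alleles, `se > 0`,
#' `eaf` strictly inside (0, 1), `pvalue` in (0, 1], `n >= 2`. Errors name
#' the first offending row.
#'
#' @param stats A tibble as returned by [read_summary_stats()].
#' @return `stats`, invisibly, if valid.
#' @export
validate_summary_stats <- function(stats) {
  req <- c("snp", "effect_allele", "other_allele", "eaf", "beta", "se",
           "pvalue", "n")
  missing <- setdiff(req, names(stats))
  check_config(
    length(missing) == 0,
    paste0("summary table lacks column(s): ", paste(missing, collapse = ", "))
  )
  bases <- c("A", "C", "G", "T")
  fail_row <- function(ok, what) {
    bad <- which(!ok | is.na(ok))
    if (length(bad) > 0) {
      rlang::abort(
        sprintf("invalid summary record at row %d: %s", bad[1], what),
        class = "mrpath_validation_error"
      )
    }
  }
  fail_row(stats$effect_allele %in% bases & stats$other_allele %in% bases,
           "alleles must be single bases A/C/G/T")
  fail_row(stats$effect_allele != stats$other_allele,
           "effect and other allele must differ")
  fail_row(stats$se > 0, "se must be > 0")
  fail_row(stats$eaf > 0 & stats$eaf < 1, "eaf must be strictly inside (0,1)")
  fail_row(stats$pvalue > 0 & stats$pvalue <= 1, "pvalue must be in (0,1]")
  fail_row(stats$n >= 2, "n must be >= 2")
  invisible(stats)
}

# duplicate rsids: keep the smallest p-value, report the rest
dedupe_summary <- function(stats) {
  if (!anyDuplicated(stats$snp)) {
    return(stats)
  }
  dups <- unique(stats$snp[duplicated(stats$snp)])
  rlang::inform(sprintf(
    "%d duplicate SNP id(s) resolved by smallest p-value: %s",
    length(dups), paste(utils::head(dups, 5), collapse = ", ")
  ))
  stats |>
    dplyr::mutate(.ord = dplyr::row_number()) |>
    dplyr::group_by(.data$snp) |>
    dplyr::slice_min(.data$pvalue, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select(-".ord")
}

#' Write summary statistics as TSV
#'
#' Writes the canonical column order `SNP, CHR, POS, EA, OA, EAF, BETA, SE,
#' P, N` so files round-trip through [read_summary_stats()].
#'
#' @param stats Summary-statistics tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(stats, path) {
  out <- tibble::tibble(
    SNP = stats$snp,
    CHR = if ("chrom" %in% names(stats)) stats$chrom else NA_character_,
    POS = if ("pos" %in% names(stats)) stats$pos else NA_integer_,
    EA = stats$effect_allele, OA = stats$other_allele,
    EAF = stats$eaf, BETA = stats$beta, SE = stats$se,
    P = stats$pvalue, N = stats$n
  )
  write_tsv_quiet(out, path)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

is_palindromic_pair <- function(a1, a2) {
  unname(COMPLEMENT[a1] == a2)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the outcome association of every SNP shared between two summary
#' tables onto the exposure's effect-allele frame. Outcome records whose
#' alleles are swapped relative to the exposure have their beta negated and
#' frequency complemented; non-matching allele pairs are reconciled by
#' strand complement before being dropped. Palindromic SNPs (A/T or C/G)
#' cannot be resolved from alleles alone: those with minor allele frequency
#' above `palindrome_maf_limit` are excluded as strand-ambiguous, the rest
#' are oriented by allele-frequency consistency between the two files.
#'
#' @param exposure,outcome Summary-statistics tibbles
#'   (see [read_summary_stats()]).
#' @param palindrome_maf_limit Palindromic SNPs with
#'   `min(eaf, 1 - eaf)` above this value are dropped (default 0.3).
#' @return A tibble of harmonized pairs with columns `snp`,
#'   `effect_allele`, `other_allele`, `beta_exposure`, `se_exposure`,
#'   `eaf_exposure`, `beta_outcome`, `se_outcome`, `is_palindromic`,
#'   `was_flipped`. Dropped SNPs and the reason are recorded in the
#'   `"dropped"` attribute.
#' @export
harmonize <- function(exposure, outcome, palindrome_maf_limit = 0.3) {
  validate_summary_stats(exposure)
  validate_summary_stats(outcome)
  check_config(
    is_single_number(palindrome_maf_limit) &&
      palindrome_maf_limit >= 0 && palindrome_maf_limit <= 0.5,
    "`palindrome_maf_limit` must be a fraction in [0, 0.5]"
  )
  exposure <- dedupe_summary(exposure)
  outcome <- dedupe_summary(outcome)

  joined <- dplyr::inner_join(
    exposure, outcome,
    by = "snp", suffix = c("_exp", "_out")
  )
  if (nrow(joined) == 0) {
    return(empty_harmonized())
  }

  rows <- purrr::pmap(
    list(
      joined$snp,
      joined$effect_allele_exp, joined$other_allele_exp,
      joined$effect_allele_out, joined$other_allele_out,
      joined$eaf_exp, joined$eaf_out,
      joined$beta_exp, joined$se_exp,
      joined$beta_out, joined$se_out
    ),
    harmonize_one,
    maf_limit = palindrome_maf_limit
  )
  kept <- dplyr::bind_rows(purrr::keep(rows, is.data.frame))
  dropped <- dplyr::bind_rows(
    purrr::map(purrr::keep(rows, is.character), function(r) {
      tibble::tibble(snp = r[["snp"]], reason = r[["reason"]])
    })
  )
  if (nrow(dropped) > 0) {
    rlang::inform(sprintf(
      "harmonize: dropped %d SNP(s) (%s)", nrow(dropped),
      paste(unique(dropped$reason), collapse = "; ")
    ))
  }
  out <- if (nrow(kept) > 0) kept else empty_harmonized()
  attr(out, "dropped") <- dropped
  out
}

empty_harmonized <- function() {
  tibble::tibble(
    snp = character(), effect_allele = character(), other_allele = character(),
    beta_exposure = double(), se_exposure = double(), eaf_exposure = double(),
    beta_outcome = double(), se_outcome = double(),
    is_palindromic = logical(), was_flipped = logical()
  )
}

harmonize_one <- function(snp, ea_x, oa_x, ea_y, oa_y, eaf_x, eaf_y,
                          beta_x, se_x, beta_y, se_y, maf_limit) {
  palindromic <- is_palindromic_pair(ea_x, oa_x)
  flipped <- FALSE

  if (palindromic) {
    # alleles are uninformative for strand; ambiguous at high MAF
    if (min(eaf_x, 1 - eaf_x) > maf_limit) {
      return(c(snp = snp, reason = "palindromic with MAF above limit"))
    }
    if (abs(eaf_x - eaf_y) > abs(eaf_x - (1 - eaf_y))) {
      beta_y <- -beta_y
      flipped <- TRUE
    }
  } else {
    same <- ea_y == ea_x && oa_y == oa_x
    swapped <- ea_y == oa_x && oa_y == ea_x
    if (!same && !swapped) {
      # try the other strand
      ea_yc <- unname(COMPLEMENT[ea_y])
      oa_yc <- unname(COMPLEMENT[oa_y])
      same <- ea_yc == ea_x && oa_yc == oa_x
      swapped <- ea_yc == oa_x && oa_yc == ea_x
    }
    if (swapped) {
      beta_y <- -beta_y
      eaf_y <- 1 - eaf_y
      flipped <- TRUE
    } else if (!same) {
      return(c(snp = snp, reason = "irreconcilable alleles"))
    }
  }

  tibble::tibble(
    snp = snp, effect_allele = ea_x, other_allele = oa_x,
    beta_exposure = beta_x, se_exposure = se_x, eaf_exposure = eaf_x,
    beta_outcome = beta_y, se_outcome = se_y,
    is_palindromic = palindromic, was_flipped = flipped
  )
}
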