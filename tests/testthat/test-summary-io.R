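test_that("summary statistics round-trip through TSV exactly", {
  stats <- make_summary(n = 2)
  path <- write_summary_file(stats)
  back <- read_summary_stats(path)
  expect_equal(back$snp, stats$snp)
  expect_equal(back$beta, stats$beta)
  expect_equal(back$se, stats$se)
  expect_equal(back$eaf, stats$eaf)
  expect_equal(back$pvalue, stats$pvalue)
  expect_equal(back$n, stats$n)
})

test_that("comma-delimited input is auto-detected", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "SNP,EA,OA,EAF,BETA,SE,P,N",
    "rs1,A,G,0.25,0.12,0.02,1e-9,10000"
  ), tf)
  got <- read_summary_stats(tf)
  expect_equal(got$beta, 0.12)
  expect_equal(got$n, 10000L)
})

test_that("row-level validation errors cite the offending row", {
  stats <- make_summary(n = 3)
  stats$se[2] <- 0
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(
    tibble::tibble(SNP = stats$snp, EA = stats$effect_allele,
                   OA = stats$other_allele, EAF = stats$eaf,
                   BETA = stats$beta, SE = stats$se, P = stats$pvalue,
                   N = stats$n),
    path
  )
  expect_error(read_summary_stats(path), "row 2",
               class = "mrpath_validation_error")
})

test_that("a column_map that omits a required field is a configuration error", {
  stats <- make_summary(n = 2)
  path <- write_summary_file(stats)
  partial <- c(snp = "SNP", effect_allele = "EA", other_allele = "OA",
               eaf = "EAF", beta = "BETA", se = "SE", n = "N")
  expect_error(read_summary_stats(path, column_map = partial), "pvalue",
               class = "mrpath_config_error")
})

test_that("missing mapped columns and unparsable numerics are rejected", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tN",
               "rs1\tA\tG\t0.2\t0.1\t0.02\t500"), tf)
  expect_error(read_summary_stats(tf), "'P'", class = "mrpath_config_error")

  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tEAF\tBETA\tSE\tP\tN",
               "rs1\tA\tG\t0.2\tnot_a_number\t0.02\t0.5\t500"), tf2)
  expect_error(read_summary_stats(tf2), "unparsable.*row 1",
               class = "mrpath_validation_error")
})

test_that("duplicate rsids keep the smallest p-value", {
  stats <- make_summary(n = 3)
  dup <- stats[1, ]
  dup$pvalue <- stats$pvalue[1] / 10
  dup$beta <- 99
  path <- write_summary_file(dplyr::bind_rows(stats, dup))
  expect_message(got <- read_summary_stats(path), "duplicate")
  expect_equal(nrow(got), 3)
  expect_equal(got$beta[got$snp == stats$snp[1]], 99)
})

test_that("harmonizing a table against itself keeps every SNP unchanged", {
  x <- make_summary(n = 6, seed = 42)
  h <- harmonize(x, x)
  expect_equal(nrow(h), 6)
  expect_false(any(h$was_flipped))
  expect_equal(h$beta_outcome, x$beta)
  expect_equal(h$beta_exposure, x$beta)
})

test_that("swapped outcome alleles flip the outcome beta and frequency", {
  exp <- make_summary(n = 1)
  out <- exp
  out$effect_allele <- exp$other_allele
  out$other_allele <- exp$effect_allele
  out$beta <- 0.2
  out$eaf <- 1 - exp$eaf
  h <- harmonize(exp, out)
  expect_equal(h$beta_outcome, -0.2)
  expect_true(h$was_flipped)
})

test_that("strand-complement mismatches are reconciled before dropping", {
  exp <- make_summary(n = 2, ea = "A", oa = "G")
  out <- exp
  out$effect_allele <- "T" # complement of A
  out$other_allele <- "C"  # complement of G
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 2)
  expect_false(any(h$was_flipped))
  expect_equal(h$beta_outcome, exp$beta)

  # complement + swap
  out2 <- exp
  out2$effect_allele <- "C"
  out2$other_allele <- "T"
  h2 <- harmonize(exp, out2)
  expect_true(all(h2$was_flipped))
  expect_equal(h2$beta_outcome, -exp$beta)
})

test_that("irreconcilable allele pairs are dropped with a log, not fatal", {
  exp <- make_summary(n = 2, ea = "A", oa = "G")
  out <- exp
  out$effect_allele[1] <- "A"
  out$other_allele[1] <- "C" # neither match, swap, nor complement
  expect_message(h <- harmonize(exp, out), "dropped 1")
  expect_equal(nrow(h), 1)
  expect_equal(attr(h, "dropped")$snp, exp$snp[1])
})

test_that("palindromic SNPs follow the MAF-0.3 exclusion rule", {
  exp <- make_summary(n = 2, ea = "A", oa = "T")
  out <- exp
  # ambiguous: MAF 0.40 > 0.3 -> excluded
  exp$eaf <- c(0.40, 0.10)
  out$eaf <- c(0.40, 0.10)
  h <- suppressMessages(harmonize(exp, out))
  expect_equal(nrow(h), 1)
  expect_equal(h$snp, exp$snp[2])
  expect_true(h$is_palindromic)
  expect_false(h$was_flipped)

  # retained palindrome is oriented by frequency consistency
  out$eaf <- c(0.40, 0.90) # 0.90 matches 1 - 0.10 better than 0.10
  h2 <- suppressMessages(harmonize(exp, out))
  expect_true(h2$was_flipped)
  expect_equal(h2$beta_outcome, -out$beta[2])
})

test_that("harmonization is idempotent on an already-aligned outcome", {
  exp <- make_summary(n = 5, seed = 7)
  out <- make_summary(n = 5, seed = 8)
  h1 <- harmonize(exp, out)
  # rebuild an outcome file already on the exposure frame
  out2 <- out
  out2$beta <- h1$beta_outcome
  out2$effect_allele <- h1$effect_allele
  out2$other_allele <- h1$other_allele
  out2$eaf <- h1$eaf_exposure
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_false(any(h2$was_flipped))
})

test_that("|beta_outcome| is invariant under allele swap of the outcome file", {
  for (seed in 1:5) {
    exp <- make_summary(n = 8, seed = seed)
    out <- make_summary(n = 8, seed = seed + 100)
    swapped <- out
    swapped$effect_allele <- out$other_allele
    swapped$other_allele <- out$effect_allele
    swapped$beta <- -out$beta
    swapped$eaf <- 1 - out$eaf
    h1 <- harmonize(exp, out)
    h2 <- harmonize(exp, swapped)
    expect_equal(abs(h2$beta_outcome), abs(h1$beta_outcome))
    expect_equal(h2$beta_outcome, h1$beta_outcome)
  }
})
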