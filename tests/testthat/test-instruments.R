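test_that("p-value selection is a strict-inequality subset filter", {
  stats <- make_summary(n = 3)
  stats$pvalue <- c(1e-6, 2e-5, 5e-9)
  kept <- select_by_pvalue(stats, 1e-5)
  expect_equal(kept$snp, stats$snp[c(1, 3)])

  expect_equal(nrow(select_by_pvalue(stats, 1)), 3)

  # boundary: p exactly equal to the threshold is excluded
  stats$pvalue <- c(1e-5, 1e-5, 0.99e-5)
  expect_equal(select_by_pvalue(stats, 1e-5)$snp, stats$snp[3])

  expect_message(select_by_pvalue(stats, 1e-300), "no records")
})

test_that("variance explained matches the closed form", {
  expect_equal(compute_variance_explained(0.5, 0.1, 0.01, 10000),
               0.009901, tolerance = 1e-6 / 0.009901)
  expect_identical(compute_variance_explained(0.3, 0, 0.01, 5000), 0)
  # symmetry in eaf about 0.5
  expect_equal(compute_variance_explained(0.2, 0.1, 0.02, 4000),
               compute_variance_explained(0.8, 0.1, 0.02, 4000))
  expect_error(compute_variance_explained(1.2, 0.1, 0.02, 4000),
               class = "mrpath_validation_error")
  expect_error(compute_variance_explained(0.2, 0.1, 0, 4000),
               class = "mrpath_validation_error")
})

test_that("F-statistic matches the closed form and boundary rule", {
  expect_equal(compute_f(0.009901, 10000), 99.98, tolerance = 0.01 / 99.98)
  expect_identical(compute_f(0, 1000), 0)
  expect_error(compute_f(1, 1000), class = "mrpath_validation_error")

  # F strictly increasing in r2 and n
  r2 <- seq(0.001, 0.05, length.out = 20)
  expect_true(all(diff(compute_f(r2, 5000)) > 0))
  ns <- seq(1000, 50000, length.out = 20)
  expect_true(all(diff(compute_f(0.01, ns)) > 0))
})

test_that("the weak-instrument filter removes F < 10 and keeps F = 10", {
  # r2 chosen so F = 10 exactly at n = 1002: r2 = 10 / (10 + n - 2)
  r2_at_10 <- 10 / (10 + 1000)
  expect_equal(compute_f(r2_at_10, 1002), 10)

  stats <- make_summary(n = 3)
  stats <- add_instrument_strength(stats)
  stats$f_statistic <- c(9.999, 10, 250)
  kept <- suppressMessages(filter_weak_instruments(stats))
  expect_equal(kept$snp, stats$snp[2:3])
})

test_that("add_instrument_strength derives r2 and F from each record", {
  stats <- make_summary(n = 5, seed = 3)
  got <- add_instrument_strength(stats)
  expect_equal(
    got$r2,
    compute_variance_explained(stats$eaf, stats$beta, stats$se, stats$n)
  )
  expect_equal(got$f_statistic, got$r2 * (stats$n - 2) / (1 - got$r2))
})

make_ld <- function(snps, r2 = 0) {
  m <- matrix(r2, length(snps), length(snps),
              dimnames = list(snps, snps))
  diag(m) <- 1
  m
}

test_that("clumping keeps the best of a correlated nearby pair", {
  stats <- make_summary(n = 2, pos = c(100000L, 150000L))
  stats$pvalue <- c(1e-8, 1e-6)
  got <- clump(stats, make_ld(stats$snp, 0.5))
  expect_equal(got$snp, stats$snp[1])

  # below the r2 threshold both survive
  got2 <- clump(stats, make_ld(stats$snp, 0.0005))
  expect_equal(sort(got2$snp), sort(stats$snp))
})

test_that("the genomic window gates the r2 rule", {
  # same spurious r2 = 0.9 but on different chromosomes: both kept
  stats <- make_summary(n = 2, chrom = c("1", "2"),
                        pos = c(100000L, 150000L))
  got <- clump(stats, make_ld(stats$snp, 0.9))
  expect_equal(nrow(got), 2)

  # same chromosome but beyond the +/- window: both kept
  stats2 <- make_summary(n = 2, pos = c(100000L, 100000L + 10000001L))
  got2 <- clump(stats2, make_ld(stats2$snp, 0.9))
  expect_equal(nrow(got2), 2)
})

test_that("clumping equals brute-force greedy enumeration on small instances", {
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(2:6, 1)
      stats <- make_summary(n = n, seed = seed,
                            chrom = sample(c("1", "2"), n, replace = TRUE),
                            pos = sample.int(2e7, n))
      snps <- stats$snp
      r2 <- matrix(runif(n * n), n, n, dimnames = list(snps, snps))
      r2 <- (r2 + t(r2)) / 2
      diag(r2) <- 1
      got <- clump(stats, r2, r2_threshold = 0.3, window_kb = 5000)
      want <- oracle_clump(as.data.frame(stats), r2,
                           r2_threshold = 0.3, window_kb = 5000)
      expect_equal(got$snp, want)
    })
  }
})

test_that("clumped output is pairwise independent within the window", {
  withr::with_seed(11, {
    n <- 30
    stats <- make_summary(n = n, seed = 11,
                          chrom = sample(c("1", "2", "3"), n, replace = TRUE),
                          pos = sample.int(5e7, n))
    r2 <- matrix(runif(n * n, 0, 0.6), n, n,
                 dimnames = list(stats$snp, stats$snp))
    r2 <- (r2 + t(r2)) / 2
    diag(r2) <- 1
    got <- clump(stats, r2, r2_threshold = 0.1, window_kb = 10000)
    # exhaustive pair scan
    for (i in seq_len(nrow(got))) {
      for (j in seq_len(nrow(got))) {
        if (i >= j) next
        same_chr <- got$chrom[i] == got$chrom[j]
        close <- abs(got$pos[i] - got$pos[j]) <= 1e7
        if (same_chr && close) {
          expect_lt(r2[got$snp[i], got$snp[j]], 0.1)
        }
      }
    }
    # every filter output is a subsequence of its input
    expect_true(all(got$snp %in% stats$snp))
  })
})

test_that("confounder screening removes strict hits only", {
  stats <- make_summary(n = 3)
  assoc <- tibble::tibble(
    snp = c(stats$snp[1], stats$snp[2]),
    trait = c("BMI", "smoking"),
    pvalue = c(1e-7, 2e-5)
  )
  got <- suppressMessages(screen_confounders(stats, assoc))
  # 1e-7 removed; 2e-5 above the 1e-5 threshold is kept
  expect_equal(got$snp, stats$snp[2:3])

  expect_equal(screen_confounders(stats, assoc[0, ]), stats)
  expect_equal(screen_confounders(stats, NULL), stats)
})
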