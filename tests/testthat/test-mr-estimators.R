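test_that("IVW recovers an exactly proportional effect with zero heterogeneity", {
  pairs <- make_pairs(bx = c(0.1, 0.2, 0.4),
                      by = c(0.05, 0.10, 0.20),
                      sy = rep(0.1, 3))
  est <- mr_ivw(pairs)
  expect_equal(est$beta, 0.5)
  expect_equal(attr(est, "q"), 0)
  expect_equal(est$method, "ivw")
})

test_that("a single SNP yields the Wald ratio with the delta-method se", {
  pairs <- make_pairs(bx = 0.2, by = 0.1, sy = 0.05)
  est <- mr_ivw(pairs)
  expect_equal(est$method, "wald")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.25)
})

test_that("IVW equals the origin-constrained normal-equation oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(2:6, 1)
      bx <- rnorm(n, 0.1, 0.05)
      by <- rnorm(n, 0.05, 0.02)
      sy <- runif(n, 0.01, 0.1)
      want <- oracle_ivw(bx, by, sy)
      got <- mr_ivw(make_pairs(bx, by, sy), variant = "fixed")
      expect_equal(got$beta, want$beta, tolerance = 1e-10)
      expect_equal(got$se, want$se, tolerance = 1e-10)
    })
  }
})

test_that("IVW with equal se reduces to ordinary origin-constrained LS", {
  withr::with_seed(4, {
    bx <- rnorm(5, 0.2, 0.1)
    by <- rnorm(5, 0.1, 0.05)
    got <- mr_ivw(make_pairs(bx, by, rep(0.03, 5)), variant = "fixed")
    expect_equal(got$beta, sum(bx * by) / sum(bx^2), tolerance = 1e-12)
  })
})

test_that("rescaling exposure betas by c rescales every estimate by 1/c", {
  withr::with_seed(9, {
    bx <- rnorm(8, 0.2, 0.08)
    by <- 0.4 * bx + rnorm(8, 0, 0.01)
    sy <- runif(8, 0.01, 0.03)
    pairs <- make_pairs(bx, by, sy)
    scaled <- make_pairs(3 * bx, by, sy)
    expect_equal(mr_ivw(scaled)$beta, mr_ivw(pairs)$beta / 3)
    expect_equal(mr_egger(scaled)$beta[1], mr_egger(pairs)$beta[1] / 3)
    expect_equal(
      mr_weighted_median(scaled, n_boot = 50, seed = 1)$beta,
      mr_weighted_median(pairs, n_boot = 50, seed = 1)$beta / 3
    )
  })
})

test_that("Egger fits the affine model exactly", {
  pairs <- make_pairs(bx = c(0.1, 0.2, 0.4),
                      by = c(0.05, 0.10, 0.20),
                      sy = rep(0.1, 3))
  est <- mr_egger(pairs)
  expect_equal(est$beta[est$method == "egger"], 0.5, tolerance = 1e-12)
  expect_equal(est$beta[est$method == "egger_intercept"], 0,
               tolerance = 1e-12)

  # constructed affine data: by = 0.02 + 0.5 * bx
  bx <- c(0.05, 0.1, 0.2, 0.3, 0.45)
  pairs2 <- make_pairs(bx, 0.02 + 0.5 * bx, rep(0.04, 5))
  est2 <- mr_egger(pairs2)
  expect_equal(est2$beta[est2$method == "egger"], 0.5, tolerance = 1e-10)
  expect_equal(est2$beta[est2$method == "egger_intercept"], 0.02,
               tolerance = 1e-10)

  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1), c(0.1, 0.1))),
               class = "mrpath_validation_error")
})

test_that("Egger equals the weighted normal-equation oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      n <- sample(3:6, 1)
      bx <- rnorm(n, 0.1, 0.2) # mixed signs exercise re-orientation
      by <- rnorm(n, 0.05, 0.1)
      sy <- runif(n, 0.02, 0.1)
      want <- oracle_egger(bx, by, sy)
      got <- mr_egger(make_pairs(bx, by, sy))
      expect_equal(got$beta[got$method == "egger"], want$slope,
                   tolerance = 1e-10)
      expect_equal(got$beta[got$method == "egger_intercept"], want$intercept,
                   tolerance = 1e-10)
    })
  }
})

test_that("weighted median interpolates the 50th weight percentile", {
  pairs <- make_pairs(bx = rep(0.1, 3), by = rep(0.05, 3), sy = rep(0.02, 3))
  expect_equal(mr_weighted_median(pairs, n_boot = 20, seed = 1)$beta, 0.5)

  # majority-valid cluster wins: ratios (0.5, 0.5, 0.5, 5, 5), equal weights
  bx <- rep(0.1, 5)
  by <- c(0.05, 0.05, 0.05, 0.5, 0.5)
  est <- mr_weighted_median(make_pairs(bx, by, rep(0.02, 5)),
                            n_boot = 20, seed = 1)
  expect_equal(est$beta, 0.5)
})

test_that("bootstrap estimators are deterministic given a seed", {
  withr::with_seed(2, {
    bx <- rnorm(10, 0.2, 0.05)
    by <- 0.3 * bx + rnorm(10, 0, 0.02)
    pairs <- make_pairs(bx, by, runif(10, 0.01, 0.05))
  })
  a <- mr_weighted_median(pairs, n_boot = 100, seed = 7)
  b <- mr_weighted_median(pairs, n_boot = 100, seed = 7)
  expect_identical(a, b)
  c1 <- mr_mode(pairs, n_boot = 100, seed = 7)
  c2 <- mr_mode(pairs, n_boot = 100, seed = 7)
  expect_identical(c1, c2)
})

test_that("SNPs with zero exposure effect are excluded from ratio estimators", {
  pairs <- make_pairs(bx = c(0, 0.1, 0.2, 0.3),
                      by = c(9, 0.05, 0.10, 0.15),
                      sy = rep(0.02, 4))
  expect_message(est <- mr_weighted_median(pairs, n_boot = 20, seed = 1),
                 "beta_exposure = 0")
  expect_equal(est$beta, 0.5)
  expect_equal(est$n_snp, 3L)
})

test_that("the mode estimator finds the modal ratio cluster", {
  bx <- rep(0.1, 5)
  by <- c(0.05, 0.05, 0.05, 0.5, 0.5) # ratios 0.5 x3, 5 x2
  est <- mr_mode(make_pairs(bx, by, rep(0.02, 5)), n_boot = 20, seed = 1)
  expect_equal(est$beta, 0.5, tolerance = 0.2)

  # identical ratios return exactly that ratio
  same <- make_pairs(rep(0.2, 4), rep(0.08, 4), rep(0.02, 4))
  expect_equal(mr_mode(same, n_boot = 20, seed = 1)$beta, 0.4)

  # doubling the bandwidth keeps the estimate inside the ratio hull
  wide <- mr_mode(make_pairs(bx, by, rep(0.02, 5)), bandwidth_factor = 2,
                  n_boot = 20, seed = 1)
  expect_gte(wide$beta, 0.5 - 1e-9)
  expect_lte(wide$beta, 5 + 1e-9)
})

test_that("Cochran's Q matches term-by-term summation and is permutation-invariant", {
  pairs <- make_pairs(bx = c(0.1, 0.2, 0.4),
                      by = c(0.05, 0.10, 0.20),
                      sy = rep(0.1, 3))
  q0 <- cochran_q(pairs, beta_ref = 0.5)
  expect_equal(q0$q, 0)
  expect_equal(q0$pvalue, 1)
  expect_equal(q0$df, 2L)

  withr::with_seed(5, {
    bx <- rnorm(3, 0.2, 0.1)
    by <- rnorm(3, 0.1, 0.05)
    sy <- runif(3, 0.02, 0.08)
  })
  p2 <- make_pairs(bx, by, sy)
  got <- cochran_q(p2, beta_ref = 0.37)
  expect_equal(got$q, oracle_q(bx, by, sy, 0.37), tolerance = 1e-10)

  perm <- p2[c(3, 1, 2), ]
  expect_equal(cochran_q(perm, beta_ref = 0.37)$q, got$q)
})
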