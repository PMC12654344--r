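# in-code fixture builders shared across test files

make_summary <- function(n = 4, seed = 1, chrom = "1",
                         pos = seq_len(n) * 100000L,
                         ea = "A", oa = "G") {
  withr::with_seed(seed, {
    tibble::tibble(
      snp = sprintf("rs%03d", seq_len(n)),
      chrom = rep_len(chrom, n),
      pos = as.integer(pos),
      effect_allele = rep_len(ea, n),
      other_allele = rep_len(oa, n),
      eaf = runif(n, 0.1, 0.45),
      beta = rnorm(n, 0, 0.1),
      se = runif(n, 0.01, 0.05),
      pvalue = runif(n, 1e-10, 0.99),
      n = 10000L
    )
  })
}

# harmonized table straight from effect vectors
make_pairs <- function(bx, by, sy, sx = rep(0.01, length(bx))) {
  tibble::tibble(
    snp = sprintf("rs%03d", seq_along(bx)),
    beta_exposure = bx,
    se_exposure = sx,
    beta_outcome = by,
    se_outcome = sy
  )
}

# identity-frame harmonized pairs from a two-sample simulation
pairs_from_sim <- function(sim) {
  tibble::tibble(
    snp = sim$exposure$snp,
    beta_exposure = sim$exposure$beta,
    se_exposure = sim$exposure$se,
    beta_outcome = sim$outcome$beta,
    se_outcome = sim$outcome$se
  )
}

write_summary_file <- function(stats, path = withr::local_tempfile(
                                 fileext = ".tsv",
                                 .local_envir = parent.frame()
                               )) {
  mrpath::write_summary_stats(stats, path)
  path
}
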