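#' Configuration for the seeded GWAS simulators
#'
#' Collects every knob of the summary-statistics generators in one
#' validated list. Defaults mirror the cohorts the package's analyses are
#' shaped around: a microbiota-scale exposure GWAS (5,959 participants),
#' a biobank-scale binary outcome (442,165), and a metabolite-scale
#' mediator GWAS (8,288). Phenotypes are on a standardized
#' (unit-variance) scale so the per-SNP standard error has the closed
#' form \eqn{1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,N}}.
#'
#' @param seed Integer root seed; every generator is a pure function of
#'   the config including this seed.
#' @param n_snps Number of instrument SNPs per panel.
#' @param n_exposure,n_outcome,n_mediator GWAS sample sizes.
#' @param maf_range Range the minor-allele frequencies are drawn from
#'   (uniform), inside (0, 0.5].
#' @param effect_sd Standard deviation of the true per-SNP exposure
#'   effects \eqn{\gamma_j \sim N(0, \mathrm{effect\_sd}^2)}.
#' @param true_theta Causal exposure-outcome effect.
#' @param theta1,theta2,direct Mediation path effects: exposure to
#'   mediator, mediator to outcome, and the direct exposure-outcome
#'   path. The implied total is `direct + theta1 * theta2`.
#' @param pleiotropy_frac Fraction of SNPs given a pleiotropic outcome
#'   effect.
#' @param pleiotropy_mean,pleiotropy_sd Moments of the pleiotropic
#'   effects, drawn in the frame where the effect allele increases the
#'   exposure (a nonzero mean is *directional* pleiotropy as MR-Egger
#'   detects it).
#' @param ld_block_size SNPs per LD block (1 = independent instruments).
#' @param ld_within_r2 Squared correlation between SNPs of one block.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_snps = 50,
                              n_exposure = 5959,
                              n_outcome = 442165,
                              n_mediator = 8288,
                              maf_range = c(0.05, 0.5),
                              effect_sd = 0.15,
                              true_theta = 0.2,
                              theta1 = 0.3,
                              theta2 = 0.4,
                              direct = 0.28,
                              pleiotropy_frac = 0,
                              pleiotropy_mean = 0,
                              pleiotropy_sd = 0,
                              ld_block_size = 1,
                              ld_within_r2 = 0) {
  cfg <- list(
    seed = as.integer(seed), n_snps = as.integer(n_snps),
    n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
    n_mediator = as.integer(n_mediator),
    maf_range = as.numeric(maf_range), effect_sd = effect_sd,
    true_theta = true_theta, theta1 = theta1, theta2 = theta2,
    direct = direct, pleiotropy_frac = pleiotropy_frac,
    pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
    ld_block_size = as.integer(ld_block_size), ld_within_r2 = ld_within_r2
  )
  check_config(cfg$n_snps >= 1, "`n_snps` must be >= 1")
  check_config(
    all(c(cfg$n_exposure, cfg$n_outcome, cfg$n_mediator) >= 2),
    "all sample sizes must be >= 2"
  )
  check_config(
    length(cfg$maf_range) == 2 && cfg$maf_range[1] > 0 &&
      cfg$maf_range[2] <= 0.5 && cfg$maf_range[1] <= cfg$maf_range[2],
    "`maf_range` must be an increasing pair inside (0, 0.5]"
  )
  check_config(cfg$effect_sd > 0, "`effect_sd` must be > 0")
  check_config(cfg$pleiotropy_frac >= 0 && cfg$pleiotropy_frac <= 1,
               "`pleiotropy_frac` must be in [0, 1]")
  check_config(cfg$pleiotropy_sd >= 0, "`pleiotropy_sd` must be >= 0")
  check_config(cfg$ld_block_size >= 1, "`ld_block_size` must be >= 1")
  check_config(cfg$ld_within_r2 >= 0 && cfg$ld_within_r2 <= 1,
               "`ld_within_r2` must be in [0, 1]")
  structure(cfg, class = "simulation_config")
}

# shared scaffolding: SNP ids, map positions, mafs, standard errors
snp_panel <- function(cfg, offset = 0L) {
  n <- cfg$n_snps
  idx <- seq_len(n) + offset
  block <- (seq_len(n) - 1L) %/% cfg$ld_block_size
  tibble::tibble(
    snp = sprintf("rs%06d", idx),
    chrom = as.character((block %% 22L) + 1L),
    # blocks sit 50 Mb apart; SNPs inside a block 10 kb apart
    pos = 1e6L + (block %/% 22L) * 50000000L +
      ((seq_len(n) - 1L) %% cfg$ld_block_size) * 10000L,
    effect_allele = "A",
    other_allele = "G",
    block = block
  )
}

panel_ld_matrix <- function(panel, within_r2) {
  n <- nrow(panel)
  m <- outer(panel$block, panel$block,
             function(a, b) ifelse(a == b, within_r2, 0))
  diag(m) <- 1
  dimnames(m) <- list(panel$snp, panel$snp)
  m
}

# observed summary table for effects `true` at sample size n
observe_stats <- function(panel, maf, true, n_samples) {
  se <- 1 / sqrt(2 * maf * (1 - maf) * n_samples)
  bhat <- stats::rnorm(length(true), true, se)
  tibble::tibble(
    snp = panel$snp, chrom = panel$chrom, pos = panel$pos,
    effect_allele = panel$effect_allele, other_allele = panel$other_allele,
    eaf = maf, beta = bhat, se = se,
    pvalue = two_sided_p(bhat / se), n = as.integer(n_samples)
  )
}

#' Simulate a two-sample MR data set with known causal effect
#'
#' Generates exposure and outcome GWAS summary statistics for
#' `cfg$n_snps` instruments: minor-allele frequencies uniform on
#' `cfg$maf_range`, true per-SNP exposure effects
#' \eqn{\gamma_j \sim N(0, \mathrm{effect\_sd}^2)}, observed effects with
#' the closed-form standardized-trait standard errors, and outcome
#' effects \eqn{\hat\beta_{y,j} \sim
#' N(\theta\gamma_j + \alpha_j, se_{y,j}^2)} where the pleiotropic
#' \eqn{\alpha_j} are nonzero for a `pleiotropy_frac` subset. The LD
#' matrix is block-diagonal per the config. Identical configs (seed
#' included) give byte-identical output.
#'
#' @param cfg A [simulation_config()].
#' @return List with `exposure` and `outcome` summary tibbles, `ld`
#'   matrix, and a `truth` list (`maf`, `gamma`, `alpha`,
#'   `pleiotropic`, `theta`).
#' @export
simulate_two_sample <- function(cfg) {
  check_config(inherits(cfg, "simulation_config"),
               "`cfg` must come from simulation_config()")
  with_seed(cfg$seed, {
    panel <- snp_panel(cfg)
    n <- cfg$n_snps
    maf <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- stats::rnorm(n, 0, cfg$effect_sd)

    n_pleio <- round(cfg$pleiotropy_frac * n)
    pleio <- rep(FALSE, n)
    if (n_pleio > 0) {
      pleio[sample.int(n, n_pleio)] <- TRUE
    }
    alpha <- rep(0, n)
    if (n_pleio > 0) {
      # directional with respect to the exposure-increasing allele
      alpha[pleio] <- sign(gamma[pleio]) *
        stats::rnorm(n_pleio, cfg$pleiotropy_mean, cfg$pleiotropy_sd)
    }

    exposure <- observe_stats(panel, maf, gamma, cfg$n_exposure)
    outcome <- observe_stats(panel, maf, cfg$true_theta * gamma + alpha,
                             cfg$n_outcome)
    list(
      exposure = exposure,
      outcome = outcome,
      ld = panel_ld_matrix(panel, cfg$ld_within_r2),
      truth = list(maf = maf, gamma = gamma, alpha = alpha,
                   pleiotropic = pleio, theta = cfg$true_theta)
    )
  })
}

#' Simulate a mediation triplet with known proportion mediated
#'
#' Builds two disjoint instrument panels — one for the exposure, one for
#' the mediator — and generates three GWAS summary tables over their
#' union. Exposure-panel SNPs influence the mediator through the
#' exposure path \eqn{\theta_1} and the outcome through
#' \eqn{\theta_{total} = direct + \theta_1\theta_2}; mediator-panel SNPs
#' influence the outcome through \eqn{\theta_2} only. The truth record
#' stores the implied total effect and proportion mediated.
#'
#' @param cfg A [simulation_config()].
#' @return List with `exposure`, `mediator`, `outcome` summary tibbles
#'   (over all SNPs), `ld`, and `truth` (`panel` membership per SNP,
#'   `theta1`, `theta2`, `direct`, `total`, `proportion` in percent, or
#'   `NA` with a flag when the total is 0).
#' @export
simulate_mediation <- function(cfg) {
  check_config(inherits(cfg, "simulation_config"),
               "`cfg` must come from simulation_config()")
  total <- cfg$direct + cfg$theta1 * cfg$theta2
  if (total == 0) {
    rlang::warn("direct + theta1*theta2 = 0: true proportion undefined")
  }
  with_seed(cfg$seed, {
    panel_x <- snp_panel(cfg, offset = 0L)
    panel_m <- snp_panel(cfg, offset = cfg$n_snps)
    # keep the two panels on disjoint genomic stretches
    panel_m$pos <- panel_m$pos + 1000000000L
    n <- cfg$n_snps

    maf_x <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    maf_m <- stats::runif(n, cfg$maf_range[1], cfg$maf_range[2])
    gamma <- stats::rnorm(n, 0, cfg$effect_sd) # exposure effects, panel X
    delta <- stats::rnorm(n, 0, cfg$effect_sd) # mediator effects, panel M

    panel <- dplyr::bind_rows(panel_x, panel_m)
    maf <- c(maf_x, maf_m)
    eff_exposure <- c(gamma, rep(0, n))
    eff_mediator <- c(cfg$theta1 * gamma, delta)
    eff_outcome <- c(total * gamma, cfg$theta2 * delta)

    exposure <- observe_stats(panel, maf, eff_exposure, cfg$n_exposure)
    mediator <- observe_stats(panel, maf, eff_mediator, cfg$n_mediator)
    outcome <- observe_stats(panel, maf, eff_outcome, cfg$n_outcome)

    list(
      exposure = exposure,
      mediator = mediator,
      outcome = outcome,
      ld = panel_ld_matrix(panel, cfg$ld_within_r2),
      truth = list(
        panel = rep(c("exposure", "mediator"), each = n),
        gamma = gamma, delta = delta, maf = maf,
        theta1 = cfg$theta1, theta2 = cfg$theta2, direct = cfg$direct,
        total = total,
        proportion = if (total == 0) NA_real_
                     else cfg$theta1 * cfg$theta2 / total * 100
      )
    )
  })
}

#' Harmonized instrument sets for the three mediation links
#'
#' Convenience wrapper turning a [simulate_mediation()] result into the
#' three harmonized tables a two-step analysis consumes, using each
#' panel's own instruments: the exposure panel for the
#' exposure-to-mediator and exposure-to-outcome links, the mediator
#' panel for the mediator-to-outcome link.
#'
#' @param sim A [simulate_mediation()] result.
#' @return List of harmonized tibbles `step1` (exposure -> mediator),
#'   `step2` (mediator -> outcome), `total` (exposure -> outcome).
#' @export
mediation_links <- function(sim) {
  is_x <- sim$truth$panel == "exposure"
  sub <- function(stats, keep) stats[keep, , drop = FALSE]
  list(
    step1 = harmonize(sub(sim$exposure, is_x), sub(sim$mediator, is_x)),
    step2 = harmonize(sub(sim$mediator, !is_x), sub(sim$outcome, !is_x)),
    total = harmonize(sub(sim$exposure, is_x), sub(sim$outcome, is_x))
  )
}

#' Simulate block-correlated taxon and metabolite tables
#'
#' Emulates a two-group (gallstone vs control) study in which selected
#' taxon-metabolite pairs carry a planted correlation: each planted pair
#' shares a latent factor built partly from the group contrast
#' (`group_loading`) and partly from sample-level noise, scaled so the
#' pair's expected correlation equals its target `r`; all other features
#' are independent standard normal noise.
#'
#' @param n_per_group Samples per group (default 8).
#' @param n_taxa,n_metabolites Feature counts (defaults 20 and 30).
#' @param planted Tibble with columns `taxon`, `metabolite` (1-based
#'   feature indices, each used at most once) and `r` (target
#'   correlation, |r| < 1). Default: two pairs at r = -0.85 and r = 0.9.
#' @param group_loading Share of the latent factor carried by the group
#'   contrast, in \[0, 1) (default 0.6); planted features thereby also
#'   differ in mean between groups.
#' @param seed Integer seed.
#' @return List with `taxa` and `metabolites` tibbles (`sample_id`,
#'   `group`, features) and `truth` (the planted table plus
#'   `group_loading`).
#' @export
simulate_omics <- function(n_per_group = 8,
                           n_taxa = 20,
                           n_metabolites = 30,
                           planted = tibble::tibble(
                             taxon = c(1L, 2L),
                             metabolite = c(1L, 2L),
                             r = c(-0.85, 0.9)
                           ),
                           group_loading = 0.6,
                           seed = 1) {
  check_config(n_per_group >= 2, "`n_per_group` must be >= 2")
  check_config(n_taxa >= 1 && n_metabolites >= 1, "need >= 1 feature per table")
  planted <- tibble::as_tibble(planted)
  if (nrow(planted) > 0) {
    check_config(all(abs(planted$r) < 1), "planted |r| must be < 1")
    check_config(
      !anyDuplicated(planted$taxon) && !anyDuplicated(planted$metabolite),
      "each feature may appear in at most one planted pair"
    )
    check_config(
      all(planted$taxon <= n_taxa) && all(planted$metabolite <= n_metabolites),
      "planted indices exceed the feature counts"
    )
  }
  check_config(group_loading >= 0 && group_loading < 1,
               "`group_loading` must be in [0, 1)")

  n <- 2L * n_per_group
  group <- rep(c("control", "gallstone"), each = n_per_group)
  g <- ifelse(group == "gallstone", 1, -1) # unit-variance group contrast

  with_seed(as.integer(seed), {
    taxa <- matrix(stats::rnorm(n * n_taxa), n, n_taxa)
    metab <- matrix(stats::rnorm(n * n_metabolites), n, n_metabolites)
    for (i in seq_len(nrow(planted))) {
      target <- planted$r[i]
      z <- group_loading * g +
        sqrt(1 - group_loading^2) * stats::rnorm(n)
      load <- sqrt(abs(target))
      resid <- sqrt(1 - abs(target))
      taxa[, planted$taxon[i]] <- load * z + resid * stats::rnorm(n)
      metab[, planted$metabolite[i]] <-
        sign(target) * load * z + resid * stats::rnorm(n)
    }
    colnames(taxa) <- sprintf("taxon_%02d", seq_len(n_taxa))
    colnames(metab) <- sprintf("metabolite_%02d", seq_len(n_metabolites))
    sample_id <- sprintf("S%02d", seq_len(n))
    list(
      taxa = dplyr::bind_cols(
        tibble::tibble(sample_id = sample_id, group = group),
        tibble::as_tibble(taxa)
      ),
      metabolites = dplyr::bind_cols(
        tibble::tibble(sample_id = sample_id, group = group),
        tibble::as_tibble(metab)
      ),
      truth = list(planted = planted, group_loading = group_loading)
    )
  })
}
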