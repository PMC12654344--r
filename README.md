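# mrpath

Two-sample Mendelian randomization (MR) along the
diet–microbiota–metabolite–disease axis, in R. `mrpath` implements the
genetic-epidemiology toolchain used to ask whether gut microbial taxa
causally influence gallstone disease (cholelithiasis) and how much of
that influence runs through circulating metabolites such as
glycodeoxycholate or N-acetylarginine:

* **Instrument selection & QC** — p-value tiers (1e-5 for microbial
  taxa, 5e-6 for metabolites, genome-wide 5e-8 for disease), greedy LD
  clumping (r² < 0.001 within a 10,000 kb window), per-SNP variance
  explained R² = 2·EAF·(1−EAF)·β² / (2·EAF·(1−EAF)·β² +
  2·EAF·(1−EAF)·SE²·N), the instrument-strength statistic
  F = R²(N−2)/(1−R²) with the conventional F ≥ 10 filter, and a
  confounder-association screen.
* **Harmonization** — allele alignment between exposure and outcome
  summary statistics, strand-complement reconciliation, and the
  palindromic-SNP rule (A/T and C/G variants with MAF > 0.3 dropped;
  the rest oriented by allele-frequency consistency).
* **Estimator battery** — IVW (weighted regression through the origin,
  multiplicative random effects by default), weighted median, MR-Egger
  (slope + pleiotropy intercept), a simple mode-based estimator,
  Cochran's Q, and MR-PRESSO global/outlier tests, combined by the
  cross-method reliability rule: a link counts as reliable only when
  IVW is significant *and* all sign-bearing estimators agree.
* **Two-step mediation** — indirect effect β₁·β₂, direct effect
  β_all − β₁·β₂, proportion mediated (β₁·β₂)/β_all with a delta-method
  interval truncated to [0, 100]%.
* **Random-effects meta-analysis** — log-OR pooling from printed 95%
  CIs with DerSimonian–Laird or REML τ², Q and I².
* **Omics integration** — BH-corrected cross-table correlation
  networks (|r| > 0.7, p < 0.05 filter) and permutation Mantel tests
  (exact enumeration available for small sample sets).
* **Seeded simulators** — summary statistics with known causal,
  pleiotropic and mediation structure, LD-block matrices, and
  group-structured taxon/metabolite tables, so the whole pipeline is
  testable without external GWAS downloads.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` methods on fitted objects, `autoplot()` for forest and
battery plots, and a single-config `run_pipeline()` orchestrator.

## Worked example

Simulate a 30-SNP exposure with a true causal effect of 0.2 on a
binary outcome, harmonize, and run the battery:

```r
library(mrpath)

cfg  <- simulation_config(seed = 42, n_snps = 30, true_theta = 0.2)
sim  <- simulate_two_sample(cfg)
pairs <- harmonize(sim$exposure, sim$outcome)
run_battery(pairs, seed = 42)
#> MR battery: exposure -> outcome (30 SNPs)
#> # A tibble: 5 × 7
#>   method              beta      se   ci_low ci_high    pvalue n_snp
#> 1 ivw              0.200   0.00485  0.191   0.210   2.23e-308    30
#> 2 weighted_median  0.201   0.00523  0.191   0.211   2.23e-308    30
#> 3 egger            0.206   0.00822  0.190   0.222   5.03e-139    30
#> 4 egger_intercept -0.00141 0.00152 -0.00439 0.00156 3.53e-  1    30
#> 5 mode             0.196   0.00668  0.183   0.209   2.19e-188    30
#> Cochran's Q = 125.444 (df 29), p = 5.819e-14
#> MR-PRESSO global p = 0.3686; 0 outlier(s)
#> Verdict: reliable
```

Every method recovers the planted 0.2; the Egger intercept is
compatible with zero (no directional pleiotropy was simulated), and
the significant Q reflects exposure-side sampling noise, which the
multiplicative random-effects IVW absorbs into its standard error.

Pooling the four published odds ratios relating the Dietary
Inflammatory Index (DII) to gallstone risk:

```r
studies <- read_meta_studies(
  system.file("extdata", "dii_meta_studies.tsv", package = "mrpath")
)
pool_random_effects(studies)
#> Random-effects meta-analysis (4 studies, tau2 REML = 0.01605)
#> Pooled OR = 1.2369 (95% CI 1.0619-1.4407), p = 0.006291
#> Heterogeneity: Q = 8.650 (df 3, p = 0.03432), I2 = 65.3%
```

A higher-DII diet is associated with ~1.24-fold higher gallstone odds
despite moderate between-study heterogeneity.

Decomposing a mediated effect from its path coefficients (here the
microbe → bile-acid → gallstone route with β₁ = −0.19, β₂ = 0.14 and
total effect −0.098):

```r
decompose(beta_total = -0.098, beta1 = -0.19, beta2 = 0.14)[
  , c("indirect", "direct", "proportion")]
#>   indirect  direct proportion
#> 1  -0.0266 -0.0714   27.14286
```

About 27% of the protective total effect runs through the mediator.

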