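---
title: "Methods behind mrpath: summary-data MR, mediation, meta-analysis and omics integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

`mrpath` packages the statistical core of a common study design in
gastrointestinal genetic epidemiology: use human GWAS summary
statistics to ask whether gut microbial abundances causally influence
gallstone disease, whether circulating metabolites mediate that
influence, and — alongside — summarise the observational evidence that
a pro-inflammatory diet raises gallstone risk and the
microbiome–metabolome co-variation seen in experimental models. This
vignette explains the models, the defaults, the numerical choices, and
what the synthetic-data tests do and do not establish.

## Two-sample MR model and assumptions

For SNP $j$ with estimated effect $\hat\beta_{x,j}$ (SE $s_{x,j}$) on
the exposure and $\hat\beta_{y,j}$ (SE $s_{y,j}$) on the outcome from
non-overlapping samples, the instrumental-variable logic requires
relevance (the SNP affects the exposure), independence (no
confounder association) and exclusion restriction (no effect on the
outcome except through the exposure). The package maps each assumption
to a concrete operation:

* relevance — p-value tiers plus the per-SNP variance explained
  $R^2$ and strength statistic $F = R^2(N-2)/(1-R^2)$, with SNPs below
  $F = 10$ removed (the boundary value is retained; the filter is
  strict below);
* independence — LD clumping against a user-supplied $r^2$ matrix and
  a confounder-association screen (any SNP with a listed-trait
  association at $p < 10^{-5}$ is dropped);
* exclusion restriction — not testable directly; Cochran's Q, the
  MR-Egger intercept and MR-PRESSO probe its failure modes.

### Estimators

IVW solves the weighted regression of $\hat\beta_y$ on $\hat\beta_x$
through the origin with weights $w_j = 1/s_{y,j}^2$. The default
*multiplicative random-effects* variant multiplies the fixed-effect
standard error by $\max(1, \sqrt{Q/(n-1)})$ — standard errors are
inflated under heterogeneity but never deflated, which keeps the
estimator conservative. A single instrument degrades to the Wald ratio
with first-order standard error $s_y/|\hat\beta_x|$.

The weighted median orders the per-SNP ratios
$\hat\beta_{y,j}/\hat\beta_{x,j}$, weights them by the inverse
first-order ratio variance $\hat\beta_{x,j}^2/s_{y,j}^2$, and
interpolates the 50th weight percentile; it is consistent while at
least half the weight comes from valid instruments. Its standard error
is a seeded bootstrap over SNPs (default 1000 resamples).

MR-Egger re-orients every SNP so $\hat\beta_x \ge 0$ (flipping both
coordinates) and fits the weighted regression *with* intercept; the
intercept estimates the average directional pleiotropy and the slope
is the bias-adjusted causal effect. The residual scale applied to the
coefficient covariance is floored at 1, matching the IVW convention.

The mode-based estimator is the *simple* mode: a normal-kernel density
over the ratio estimates with bandwidth equal to a Silverman plug-in
rule times a user factor (default 1), whose argmax is the estimate.
The literature offers several mode variants (simple, weighted,
penalised); the simple mode with a plug-in bandwidth was chosen as the
least-parameterised member of the family, with the bandwidth factor
exposed so sensitivity to smoothing is one argument away. Identical
ratios short-circuit to that ratio exactly.

MR-PRESSO compares the observed leave-one-out weighted residual sum of
squares against a parametric null: each simulation redraws
$\hat\beta_x^\ast \sim N(\hat\beta_x, s_x^2)$ and
$\hat\beta_y^\ast \sim N(\hat\beta_{loo}\hat\beta_x, s_y^2)$ and
recomputes the statistic, so both sampling layers enter the null.
Per-SNP outlier p-values use the add-one permutation floor
$1/(n_{sim}+1)$ and are Bonferroni-corrected over the instrument
count; with the default 1000 simulations the smallest achievable
corrected p-value stays well below the 0.05 family level for typical
instrument counts (with fewer than ~400 simulations a 20-SNP outlier
test could never reject — a floor worth knowing when reducing
simulation counts). When outliers are flagged, the IVW estimate is
recomputed without them.

### The reliability rule

`run_battery()` encodes the cross-method concordance convention: a
link is *reliable* only if the IVW p-value is below `alpha` (default
0.05) **and** the signs of IVW, weighted median, Egger slope and the
PRESSO-corrected estimate (when produced) agree. The mode estimator is
reported but does not enter the sign rule. With fewer than 3 (Egger,
median, mode) or 4 (PRESSO) instruments the battery runs what it can
and sets `degraded = TRUE`. `bidirectional()` applies the same battery
in both directions and labels the result unidirectional,
bidirectional, or none; an empty instrument set in one direction is
reported as such without affecting the other.

## Harmonization choices

Allele alignment follows standard practice where the underlying study
protocols are typically silent, and the package documents its
defaults rather than guessing intent:

* outcome records whose alleles are swapped relative to the exposure
  have $\hat\beta_y$ negated and EAF complemented;
* non-matching pairs are first tried on the opposite strand
  (A/G vs T/C) before being dropped with a log entry — dropping is
  never fatal;
* palindromic SNPs (A/T, C/G) with $\min(\text{EAF}, 1-\text{EAF}) >
  0.3$ are excluded as strand-ambiguous; the remainder are oriented by
  allele-frequency consistency (the outcome is flipped when
  $|EAF_x - EAF_y| > |EAF_x - (1-EAF_y)|$);
* duplicate rsids within a file keep the smallest p-value.

## Two-step mediation

With $\beta_1$ (exposure→mediator), $\beta_2$ (mediator→outcome,
univariable — no multivariable adjustment is attempted) and
$\beta_{all}$ (total), the indirect effect is $\beta_1\beta_2$, the
direct effect $\beta_{all} - \beta_1\beta_2$ (so additivity holds to
machine precision by construction), and the proportion mediated
$(\beta_1\beta_2)/\beta_{all}$. The proportion is *reported as a
magnitude percentage* with a separate `sign_consistent` flag: study
tables in this literature print positive proportions even when the
indirect and total effects have opposite printed signs, and carrying
the ambiguity in a flag is more honest than silently choosing a sign
convention. Its standard error comes from the delta method treating
the three estimates as independent (they derive from disjoint
instrument sets), and the 95% interval is truncated to $[0, 100]\%$,
mirroring the hard zero floor of published intervals. A zero total
effect leaves the proportion undefined (flagged) while the point
decomposition is still returned. `two_step()` only reports a
proportion when both the step-1 and step-2 batteries pass the
reliability rule.

## Random-effects meta-analysis

Study odds ratios enter as printed values with 95% CIs; the log-OR
standard error is $(\ln CI_{high} - \ln CI_{low})/(2 \times 1.959964)$
— the full normal quantile, matching published software, rather than
the rounded 1.96 (a ~0.002% difference, documented because it is
occasionally audible in the fourth decimal). Heterogeneity uses the
fixed-effect Q with $I^2 = \max(0, (Q - df)/Q) \cdot 100$ — the
Q-based definition, so $I^2$ does not depend on the $\tau^2$
estimator. $\tau^2$ itself is DerSimonian–Laird (closed form) or REML
(profiled restricted likelihood maximised with `stats::optimize` at
tolerance 1e-12, with an explicit boundary check at 0). **REML is the
default**: on the shipped four-study DII table it reproduces the
published pooled interval to the printed precision, and it is the
default of the contemporary R meta-analysis stack; DL remains one
argument away and the two agree within the tolerance any downstream
consumer of this table should allow. No Hartung–Knapp adjustment is
applied. A single study passes through with $\tau^2 = 0$ and a
warning.

## Omics integration

`correlate_features()` computes all cross-table Pearson or Spearman
correlations (Spearman p-values use the asymptotic approximation, so
ties are tolerated), adjusts the *full* pair family with
Benjamini–Hochberg, and marks pairs passing $|r| > 0.7$ and raw
$p < 0.05$ — the conventional network filter; the BH q-value is
reported alongside so callers can filter on either. `mantel_test()`
correlates lower-triangle distances and permutes rows/columns of the
second matrix simultaneously; the p-value is one-sided (greater) with
the add-one correction, and an exhaustive mode enumerates all $n!$
permutations for up to 7 samples (there the identity permutation is
part of the enumeration, giving the exact test). Euclidean and
Bray–Curtis distance builders are provided; the choice of distance is
deliberately the caller's, since module eigenvalue structures and
abundance tables warrant different metrics.

## What the simulators emulate — and what they do not

`simulate_two_sample()` draws MAFs uniformly, per-SNP exposure effects
$\gamma_j \sim N(0, 0.15^2)$, and observed effects with the
standardized-trait closed-form standard error
$1/\sqrt{2\,\text{maf}(1-\text{maf})N}$. Default sample sizes mirror
the cohorts this design is built around: 5,959 (microbiota-scale
exposure GWAS), 442,165 (biobank-scale binary outcome) and 8,288
(metabolite-scale mediator GWAS). The default effect scale gives
median instrument strength comfortably above the $F = 10$ bar at the
exposure sample size, emulating a post-selection instrument panel
rather than a genome-wide pool. Pleiotropic effects are drawn *in the
frame where the effect allele increases the exposure*
($\alpha_j = \text{sign}(\gamma_j) \cdot N(\mu_\alpha,
\sigma_\alpha^2)$): with symmetric $\gamma$, a fixed-frame directional
$\alpha$ would cancel under MR-Egger's re-orientation and no estimator
could see it, so this frame is the one in which "directional
pleiotropy" is well defined. LD matrices are block-diagonal with a
configurable within-block $r^2$.

`simulate_mediation()` uses two disjoint panels — exposure
instruments, carrying the total effect
$\theta_{direct} + \theta_1\theta_2$ on the outcome, and mediator
instruments carrying $\theta_2$ — so the three links can be estimated
from valid instruments. The default paths ($\theta_1 = 0.3$,
$\theta_2 = 0.4$, direct $= 0.28$) imply a 30% mediated proportion,
the order of magnitude of the published microbe→metabolite→gallstone
routes (≈25–28%).

`simulate_omics()` plants taxon–metabolite pairs at target
correlations via shared latent factors partly loaded (default 0.6) on
the gallstone/control contrast, so planted features also separate the
groups — emulating the case–control structure of an
8-vs-8 experimental design at the published magnitudes
($|r| \approx 0.85$–0.9).

None of the generators model: overlapping GWAS samples, realistic LD
from reference panels, winner's-curse selection of instruments,
non-normal effect distributions, compositionality or zero-inflation of
abundance data, or batch structure. Tests passing on these simulators
therefore establish *statistical correctness of the estimators under
their stated models*, not robustness to every failure mode of real
summary statistics.

## Numerical conventions and degenerate inputs

* p-values are two-sided normal except Q (upper-tail chi-square) and
  the permutation/simulation tests (add-one corrected, one-sided);
  they are floored at the smallest positive double rather than
  reported as 0.
* 95% intervals use $z = 1.959964$ throughout.
* Clumping ties on p-value break by smaller position, then
  lexicographic rsid, making the output deterministic; the genomic
  window is $\pm$`window_kb` from the index SNP, inclusive, and gates
  the $r^2$ rule (a recorded $r^2$ across chromosomes is ignored).
* SNPs with $\hat\beta_x = 0$ are excluded from ratio-based
  estimators with a log entry; an all-zero outcome gives IVW $p = 1$.
* Every stochastic routine takes an explicit integer seed and restores
  the caller's RNG state (`withr::with_seed`); identical inputs give
  byte-identical outputs.

## Problem sizes used by the test suite

The shipped tests run the estimator calibrations at 200 replicates
(IVW bias), 1000 replicates (type-I error), 100 replicates (PRESSO
outlier recovery, 1000 simulations each), 200 replicates (mediation
recovery at GWAS sizes of 1–2 × 10⁵, where weak-instrument dilution
is negligible relative to Monte-Carlo error) and 100 seeds for the
planted-correlation recovery — sizes chosen so each property is
measured with a Monte-Carlo error several times smaller than the
tolerance it is tested against.

## Known limitations

* No multivariable MR: the mediator→outcome path is univariable, so
  mediator estimates inherit any exposure-shared pleiotropy.
* No Steiger filtering or CAUSE-style model comparison.
* LD matrices are consumed, not computed; there is no reference-panel
  machinery or proxy-SNP lookup.
* The meta-analysis layer handles a single endpoint (no subgroups,
  meta-regression or publication-bias tests).
* The proportion-mediated interval is a delta-method approximation;
  for totals near zero it is unstable, which the `proportion_defined`
  flag makes explicit rather than hiding.
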