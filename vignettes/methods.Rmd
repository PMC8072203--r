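---
title: "Methods: estimators, diagnostics and design choices in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, diagnostics and design choices in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

`mrpipe` implements a complete two-sample Mendelian randomization (MR)
workflow for metabolite panels against a binary disease outcome, plus the
multivariable Bayesian model-averaging layer needed when exposures are
strongly genetically correlated, and a one-sample 2SLS path for
individual-level replication. This vignette is the package's own account of
the statistics it implements: the models, their assumptions, the tunable
parameters, the numerical conventions, and what the simulation-based tests
do and do not establish.

## The instrumental-variable model

A SNP `G` is a valid instrument for exposure `X` on outcome `Y` when it is
(i) robustly associated with `X`, (ii) independent of confounders of the
`X`–`Y` relationship, and (iii) associated with `Y` only through `X`
(exclusion restriction). Under these assumptions the per-SNP Wald ratio
`by_j / bx_j` estimates the causal effect of `X` on `Y` — here log-odds of
disease per 1 SD of metabolite — and the estimators below are different
ways of pooling J such ratios with different robustness to violations of
(iii).

### Instrument selection

`select_instruments()` applies row-wise filters: genome-wide significance
(`p < 5e-8`), a per-SNP F-statistic of at least 10 to limit weak-instrument
bias, and minor-allele frequency of at least 0.01. The F statistic is
computed as `(beta/se)^2`, the standard summary-data approximation when no
per-SNP R² is published; a simulation test confirms it tracks
`(n-2) R²/(1-R²)` from an explicit genotype regression to within a few
percent. An exposure retaining fewer than `min_snps` instruments is flagged
excluded rather than analysed: a two-instrument exposure cannot support the
estimators' minimum degrees of freedom, and small instrument sets are badly
underpowered. The default `min_snps = 3` sits between a two-SNP exposure
(excluded for power) and the five-SNP exposures that remain analysable; it
is a configuration value, not a law.

Two further exclusions protect exchangeability: variants inside a
configured genomic region (the ApoE locus on chromosome 19 ships as two
named presets, because the interval is genuinely a configuration choice —
`apoe_region("printed")` at 4.50–4.58 Mb and `apoe_region("grch37")` at the
conventional ~45.4 Mb locus; neither is hard-coded), and variants reaching
genome-wide significance in the outcome GWAS. Clumping (`ld_clump()`)
greedily keeps the best-p SNP per LD block at `r² > 0.001`, against a
user-supplied LD table — the package never queries a reference panel, and
pairs absent from the table are treated as independent with a logged
warning.

### Harmonization

All estimators assume exposure and outcome effects refer to the same
allele. `harmonize_pair()` resolves label swaps (negate the outcome beta,
complement its frequency) and reverse-strand codings (base-complement
first). Palindromic SNPs (A/T, C/G) are ambiguous: the default
`assume-forward` mode treats both GWAS as forward-strand coded and keeps
them, which is the primary-analysis convention when the source GWAS are
known to be consistently coded; the `drop-noninferable` sensitivity mode
drops palindromes whose MAF exceeds 0.40 on either side (near 0.5,
frequency cannot identify the strand) and orients the rest by frequency
agreement. When the outcome file carries no allele frequencies — common for
meta-analysed case/control GWAS — the exposure frequency stands in for
palindromic inference. Matching is by rsID only; the source catalogs are
rsID-keyed and positional matching across builds is out of scope.
Duplicated rsIDs keep the smallest-p row, with a warning. Every drop
carries an action tag and the kept + dropped counts reconcile exactly with
the input — a property the test suite asserts.

## Univariable estimators

With weights `w_j = 1/sy_j²` on the regression scale:

* **IVW** is weighted least squares of `by` on `bx` through the origin.
  The package defaults to *multiplicative random effects*: the fixed-effect
  SE is inflated by `max(1, sqrt(Q/(J-1)))`, so between-instrument
  heterogeneity widens the interval but can never narrow it. This matches
  the dominant convention of two-sample MR tooling; `model = "fixed"` is a
  flag away, and every result records which variant ran. Measured over
  2000 null simulations the default test rejects at ~4%, inside the
  [0.03, 0.07] acceptance band (the mild conservatism is the price of the
  random-effects floor).
* **MR-Egger** frees the intercept; the slope is consistent under the
  InSIDE assumption (pleiotropic effects independent of instrument
  strength) and the intercept estimates mean directional pleiotropy.
  Instruments are internally oriented so all `bx ≥ 0` — the fit is not
  invariant to per-SNP sign flips otherwise — and SEs carry a residual
  scale factor floored at 1, with t(J−2) p-values for small-J robustness.
* **Weighted median**: per-SNP ratios are sorted, inverse-variance weights
  normalized, and the estimate interpolated at cumulative weight 0.5
  evaluated at interval midpoints. Its SE is a parametric bootstrap
  (default 5000 replicates, seed required): betas are redrawn from normals
  centred on the observations and the median recomputed.
* First-order weights (outcome variance only) are used throughout, in both
  the regression weights and the ratio-scale weights `bx²/sy²`; the
  estimator definitions condition on outcome variance alone, and exposure
  uncertainty is second-order for strong (F ≥ 10) instruments.

Sensitivity tooling: `cochran_q()` (Q on J−1 df; p < 0.05 flags
heterogeneity), `mr_leave_one_out()` (flags SNPs whose removal crosses
p = 0.05 or flips the sign), `funnel_data()` (plot-ready, no inference),
and `mr_presso()`.

### MR-PRESSO

The global test measures total horizontal pleiotropy through a predictive
residual sum of squares: each SNP's outcome beta is compared to the
fixed-effect IVW slope fitted on the other J−1 SNPs. Its null distribution
is simulated parametrically (betas redrawn around the leave-one-out fitted
model), with add-one smoothing so the p-value is bounded below by
`1/(n_sim+1)`. Per-SNP outlier p-values use each SNP's own simulated
residual distribution, Bonferroni-thresholded at `0.05/J` — note this means
`n_sim` must exceed `J/0.05` for a flag to be reachable at all, which is
why the default is `n_sim = 1000` at typical J. The outlier-corrected
estimate is exactly the package IVW on the non-flagged subset, and the
distortion test compares the raw-vs-corrected displacement against the
displacement from removing equally many random SNPs. With a fixed seed the
whole result is bit-reproducible.

## Multivariable MR by Bayesian model averaging

When exposures are near-duplicates genetically (NMR lipoprotein
subfractions commonly correlate above 0.95), multivariable regression is
ill-conditioned and univariable results cannot separate family-wide signal
from subfraction-specific effect. The package's answer has two stages.

**Pruning.** `prune_by_rg()` iteratively finds the most-correlated pair
above the threshold (default rg > 0.95) and drops the lower-priority
member; priority is caller-supplied (the pipeline uses univariable IVW
|z|), and ties break lexicographically so the procedure is deterministic.
The exact stepwise criteria used in any given published analysis are rarely
fully specified; this rule is the package's documented convention, with the
threshold and priority both configurable.

**Model averaging.** For the J×K matrix of exposure effects, scale rows by
`1/sy` (unit-variance noise) and columns to unit norm — the column
standardization makes one prior effect variance `sigma2` comparable across
exposures of different instrument strength. For a subset S, the marginal
likelihood of `y = X_S θ_S + ε`, `θ_S ~ N(0, sigma2 I)`, is closed-form;
the package evaluates it through the |S|-dimensional Cholesky (Sylvester's
identity avoids any J×J determinant). Posterior model probabilities
combine the ML with an independent-inclusion prior (default
`prior_p = 0.1`, i.e. an expected model size of K/10); MIP sums pp over
models containing an exposure; MACE averages the *posterior-mean* (ridge)
conditional effect, zero when excluded — so MACE is deliberately shrunk
toward the null and should be read for direction and relative magnitude,
not as an unbiased effect size. Defaults `prior_p = 0.1`,
`sigma2 = 0.25`, `z = 10000` follow the established usage of the method.

Enumeration is exhaustive for K ≤ 16 (512 fits at K = 9, exact posteriors,
no Monte-Carlo error), although a seeded shotgun stochastic search
(add/delete/swap Metropolis proposals, normalization over distinct visited
models) is retained for larger K and reproduces exhaustive MIPs to within
0.02 at `z = 10000` on the K = 9 test fixture.

**Diagnostics.** For every model with pp above `pp_min` (default 0.1),
`model_diagnostics()` fits the weighted subset regression (no prior — the
diagnostics describe the data, not the posterior) and reports per-SNP
heterogeneity contributions `q_j = (by_j − fitted_j)²/sy_j²` and Cook's
distance, flagged at `q > 10` and `cd > 4/J` (0.19 at J = 21 instruments,
the standard rule of thumb). Cook's distance is verified in tests against
the brute-force delete-one-refit definition at 1e-10. `rerun_without()`
repeats the model average with flagged instruments omitted and pairs
before/after MIPs.

## One-sample 2SLS

`mr_two_stage()` regresses the (square-root transformed, then
standardized) metabolite on all instrument dosages *in controls only* —
fitting the first stage in cases as well risks selection and
reverse-causation bias when both stages share individuals — then predicts
the genetically instrumented exposure for everyone and fits a logistic
second stage. The paper-of-record convention for such analyses reports
ORs, implying a logistic second stage; a linear-probability option exists
for diagnostics. Two conventions are worth stating explicitly:

* "Weighting instruments by strength" cannot change an unpenalized
  multiple regression (column scaling is absorbed by the coefficients), so
  per-IV variance-explained weights enter through the combined
  instrument-strength F: `F = Σ v_j F_j / Σ v_j` with `v_j = R_j²` from
  univariate first-stage fits; F < 10 flags weak instruments.
* The second-stage SE is not corrected for first-stage estimation error;
  the result object records `se_uncorrected = TRUE`. Coverage simulations
  (500 cohorts, n = 5000, true log-OR 0.4) still achieve ≥ 90% at nominal
  95%, and null p-values are uniform by Kolmogorov–Smirnov at 500
  replicates.
* The transform order is sqrt-then-standardize; the reverse order is one
  flag away and recorded, but generally impossible on real data (negative
  standardized values cannot be rooted).

## Multiplicity

`effective_tests()` estimates the effective number of independent tests
among correlated exposures from the eigenvalues of their correlation
matrix (Li–Ji convention: each eigenvalue contributes its integer part as
an indicator plus its fractional part; eigenvalues are rounded at 1e-10
before flooring so an eigenvalue of exactly K is not split by
floating-point error). `adjusted_threshold()` divides alpha by Meff and
reports two significant figures alongside full precision. The Nyholt
variant is available behind a flag; which convention a given published
threshold used is often unknowable, so the choice is documented
configuration, not a claimed reproduction.

## The synthetic-data module

`simulate_two_sample()` draws J independent instruments (no LD —
instruments are post-clumping by construction), true exposure effects
multivariate-normal across K exposures under a caller-supplied latent
correlation, and outcome effects `Σ_k θ_k bx_jk + α_j`, where `α_j` is a
direct (pleiotropic) effect carried by a configurable invalid fraction,
mean-zero when balanced. Binary-outcome effects are simulated directly on
the log-odds scale — the scale on which the estimators consume them —
rather than through a liability-threshold conversion that the summary-data
workflow could not identify anyway. Sampling noise uses the standard
approximation `se = 1/sqrt(2 maf (1-maf) n)`. Defaults are fixed at the
study conditions the package is built around: J = 21 instruments,
exposure GWAS n = 24,925, outcome GWAS n = 63,926 (non-overlapping by
construction), effect SD 0.1 (strong instruments, median F ≈ 90), MAF in
[0.05, 0.5]. Variants are emitted oriented to the allele that raises the
primary exposure, matching curated mQTL convention — this matters:
directional pleiotropy is only "directional" relative to an orientation,
and with sign-symmetric instrument effects it would cancel in ratio space.
Allele swaps, strand flips and palindromic pairs are emitted at
configurable rates so harmonization is genuinely exercised end to end.

`simulate_cohort()` (defaults n = 894, 57.6% cases, 10 instruments at 2%
variance explained each — deliberately weak-ish, like a small clinical
cohort) generates Hardy–Weinberg dosages, an additive exposure, and a
logistic outcome whose intercept is solved numerically to hit the target
case fraction. `simulate_rg()` builds factor-model correlation matrices
(within-block loading `sqrt(rg)`), positive semidefinite by construction
even with added loading noise.

What the synthetic module does *not* emulate: LD between instruments,
sample overlap between the two GWAS, liability-scale case/control
ascertainment effects, winner's-curse in instrument selection, and
population stratification. Passing tests therefore certify the estimators'
statistical behaviour under the stated generating model, not robustness to
those real-data pathologies.

## Numerical conventions and degenerate inputs

* Weighted-median interpolation uses cumulative weights at interval
  midpoints with boundary clamping (a ratio below the first midpoint
  returns the smallest ratio).
* Egger SEs and the IVW random-effects factor floor the residual scale at
  1; exact fits (zero residuals) are handled explicitly, including zeroing
  Cook's distances when the residual scale is at machine precision (the
  statistic is scale-free and would otherwise return noise).
* One instrument delegates IVW to the Wald ratio; `J < 3` refuses Egger
  and the weighted median; `J < 4` refuses MR-PRESSO; multivariable
  harmonization requires `J ≥ K + 2`.
* All stochastic steps (weighted-median bootstrap, PRESSO simulations,
  shotgun search, every generator) take explicit seeds, run on a local RNG
  stream that leaves the caller's `.Random.seed` untouched, and are
  bit-reproducible; the pipeline config refuses to enable a stochastic
  step without a seed. Config hashes cover the analytical settings but not
  the output directory, so re-runs into different directories compare
  equal.

## Problem sizes used by the test and acceptance suites

The simulation studies are sized for exactness where it is cheap and
Monte-Carlo adequacy where it is not: oracle-equivalence checks run on
single small datasets (J = 4–21) at tolerances 1e-4 to 1e-12; calibration
uses 2000 null datasets for IVW/Q and 500 cohorts for 2SLS; recovery uses
500 datasets for coverage and bias contrasts (weighted-median bootstrap at
300 replicates there — SE precision is not the quantity under test), 20
seeded runs for PRESSO outlier detection, and 100 panels for MR-BMA
ranking on the K = 9 / J = 21 geometry. These sizes give binomial
standard errors comfortably inside the acceptance margins while keeping
the full suite within a few minutes on one core.

## Known limitations

* No Steiger filtering, mode-based estimators, or
  contamination-mixture/CAUSE models; no multivariable PRESSO.
* Genetic correlations are consumed, never estimated (no LDSC); LD proxies
  come from a user-supplied table, never a panel query; no liftover.
* The 2SLS SE ignores first-stage uncertainty (flagged in the result);
  with very weak instruments the coverage claim above will degrade.
* MACE is shrunk by construction; treat rankings (MIP) as the primary
  multivariable output.
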