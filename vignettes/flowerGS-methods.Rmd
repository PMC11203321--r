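---
title: "Models and methods behind flowerGS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind flowerGS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

flowerGS analyses flowering time in multi-parent doubled-haploid (DH)
maize panels: variance components and heritability from multi-environment
trials, multi-locus GWAS, candidate-gene windows, and RR-BLUP genomic
prediction — plus a simulator that generates panels with the same
statistical structure. This vignette records the models, the tunable
parameters and their defaults, the numerical choices, and the places
where a design was genuinely open and we had to pick.

## 1. The trial model, variance components, and heritability

Phenotypes follow the classical two-way model

$$y_{ijk} = \mu + g_i + e_j + (ge)_{ij} + \varepsilon_{ijk},$$

with line effects $g_i \sim N(0, \sigma^2_g)$, fixed environment effects
$e_j$, interaction $(ge)_{ij} \sim N(0, \sigma^2_{ge})$ and plot error
$\varepsilon_{ijk} \sim N(0, \sigma^2_e)$; all variances are in days².
Treating environments as fixed and lines (and their interaction) as
random matches the entry-mean heritability formula below: the denominator
is the variance of a line-mean over $E$ environments and $R$ replicates.

On **balanced** data `fit_variance_components()` uses the closed-form
expected-mean-squares solution
($\hat\sigma^2_e = MSE$, $\hat\sigma^2_{ge} = (MS_{GE}-MSE)/R$,
$\hat\sigma^2_g = (MS_G-MS_{GE})/(RE)$), truncated at zero with a warning
when an estimate would go negative (the REML boundary). On unbalanced
data it fits the same model by REML via `lme4::lmer`; on balanced data
with interior estimates the two routes coincide (a test asserts agreement
to ~1e-6), so the closed form doubles as an independent oracle for the
iterative fit.

Entry-mean broad-sense heritability is

$$H^2 = \frac{\sigma^2_g}{\sigma^2_g + \sigma^2_{ge}/E + \sigma^2_e/(ER)}.$$

**The replicate constant R = 2.** The published trial reports E = 4
environments but not the replicate count. R = 2 is the unique small
integer for which this formula reproduces all three published
heritability percentages (82.75 / 86.09 / 85.26) from the published
variance components exactly to two decimals, so the package adopts it as
a derived design constant; it is an explicit argument everywhere it
matters.

**BLUPs.** `compute_blups()` solves Henderson's mixed-model equations at
the estimated components (sparse `Matrix` solve; environments enter with
sum-to-zero contrasts so the intercept is the grand mean) and reports
$\hat\mu + \hat g_i$. With a single replicate per line-environment cell
the interaction is confounded with the plot error, so $\sigma^2_{ge}$ is
folded into the residual instead of fitting an unidentifiable random
term; the resulting shrinkage of a line mean is
$\sigma^2_g/(\sigma^2_g + (\sigma^2_{ge}+\sigma^2_e)/E)$. A small ridge
floor (1e-8·n) keeps the equations nonsingular in the noise-free limit,
where BLUPs converge to raw entry means.

## 2. The DH panel simulator

The generator emulates a panel of ~379 DH lines derived from 21 F1
crosses of inbred founders, genotyped at biallelic SNPs on 10
chromosomes:

- **Founders** (`simulate_founders()`): binary haplotypes with per-marker
  allele frequencies Uniform(0.1, 0.9); markers evenly spaced on a
  150 cM genetic map per chromosome, physical coordinates at ~1 Mb/cM.
- **Meiosis** (`simulate_dh_population()`): Haldane's no-interference
  model — crossover counts Poisson with mean equal to map length in
  Morgans, positions uniform in cM — chosen because it has a closed-form
  recombination-fraction oracle ($r = (1-e^{-2d})/2$) that the test suite
  checks directly. Each DH line is one doubled gamete: every call is
  homozygous (dosage 0/2) and every haplotype is a mosaic of exactly its
  two parental founders (both asserted as invariants).
- **Traits** (`trait_architecture()`): one major QTL plus geometrically
  decaying minor effects, shared across the three traits, with minor
  effect vectors correlated across traits (defaults 0.90, DTT–DTS 0.88,
  DTP–DTS 0.95, mirroring the observed correlation ordering of
  sequential flowering stages). The major-QTL effect is calibrated
  against realized dosage variances so its phenotypic variance explained
  is ≈ 0.15 at the implied heritability — the size of the largest locus
  reported for these traits. Defaults `n_qtl = 300`, `decay = 0.995`
  give a realistically polygenic background (all-marker prediction
  accuracy well below its oligogenic ceiling); the trend experiments in
  the acceptance suite use an explicit 50-QTL oligogenic architecture
  where an interior top-k optimum is the expected behaviour.
- **Phenotypes** (`simulate_phenotypes()`): the genetic score is centered
  and rescaled so its sample variance equals the target $\sigma^2_g$
  *exactly* (tested at 1e-9), making downstream recovery tests sharp.
  Environment main effects are fixed offsets drawn once per environment
  (sd 6 days, the spread seen between winter-nursery and summer sites);
  they cancel in entry means. Because the three traits are scored on the
  same plots, the G-by-E and residual deviations are drawn *correlated
  across traits* with the architecture's trait correlation matrix —
  without this, BLUP correlations are bounded by the product of
  reliabilities (~0.85) and can never reach the 0.95 observed between
  DTP and DTS. Default trait means (60.6, 65.0, 66.3 days) and variance
  components (13.61/9.22/4.26 etc.) reproduce the published
  multi-environment summary scale.
- **Missingness** (`inject_missingness()`) is injected separately and
  uniformly at random; real genotyping dropout is clustered, which only
  makes the missing-rate filter's job easier here.

What the simulator does *not* emulate: linkage maps with real marker
density gradients, allele-frequency clines among founders, epistasis or
dominance (DH lines cannot express the latter), spatial field trends, or
clustered missingness. Tests passing on these panels therefore establish
the *methods'* correctness and calibration, not field-data performance.

## 3. Genotype QC

`filter_markers()` applies the two published filters sequentially —
missing rate strictly below 0.20 first, then MAF strictly above 0.05
computed on observed calls only — with both removal counts recorded in
the `QcReport` so the accounting is auditable. Strict inequalities follow
the stated thresholds ("MR < 20%", "MAF > 0.05"); a marker exactly at a
threshold is removed. Mean imputation is used (`impute_mean()`) because
DH homozygosity leaves little for model-based imputation to exploit at
desk scale; the function is an isolated swap point. PC covariates come
from `prcomp` on the column-centered dosage matrix with a fixed sign
convention (largest-magnitude loading positive) so scores are invariant
to marker order.

## 4. Multi-locus association scans

Both scans share one skeleton around an exact-OLS inner scan
(Frisch–Waugh residualization; two-sided t-test p-values; markers with no
residual variance after conditioning are flagged degenerate with p = 1):

1. scan all markers with the current pseudo-QTN set S (plus 3 PCs) as
   fixed covariates;
2. screen candidates at the relaxed threshold
   `relax_factor × alpha/m` (default 100×, capped at 0.01);
3. re-select S among candidates by information criterion;
4. iterate until S stabilizes (a revisited set counts as stabilized; cap
   `max_iterations = 10`, non-convergence flagged).

The **bin variant** keeps the best candidate per 10 Mb genomic bin and
grows S greedily; the **LD variant** takes screen survivors in p order,
discards any with squared allelic correlation above `ld_r2_max = 0.7`
with an already-kept candidate, and selects the criterion-minimizing
prefix. Final p-values come from the last conditioned scan; pseudo-QTNs
receive their coefficient p-values from the final joint model.
Significance is always declared at Bonferroni $\alpha/m$. The defaults
`bin_size = 10 Mb` and `ld_r2_max = 0.7` are configuration choices (the
underlying tools' internals are not published at this level); they are
recorded in the output metadata.

**Why extended BIC.** Model selection among m ≫ n candidate markers with
the ordinary BIC (penalty log n per term) admits markers at p ≈ 1e-3 —
and among thousands of markers several such markers always exist by
chance. In a structured multi-parent panel those spurious pseudo-QTNs
jointly reconstruct family structure, and conditioning the true QTN on
them in the final joint model can push its p-value above the genome-wide
threshold: in planted-QTL simulations (379 lines × 5,000 markers, 15%
PVE) plain BIC lost the locus in roughly a third of replicates. The
selection criterion is therefore the extended BIC (Chen & Chen 2008),
BIC + 2γk·log m with γ = 1 by default — the standard correction for this
regime — which removed the failures while leaving the family-wise error
rate at zero under the null in the same simulations. `ebic_gamma = 0`
restores the plain BIC.

**PVE.** The published per-SNP R² is not defined operationally; flowerGS
defaults to the squared partial correlation (drop-one RSS ratio against
the model with PCs and the other significant SNPs), with marginal R²
available via `pve_type = "marginal"`. Both are in [0, 1]; the choice is
recorded in the configuration.

## 5. Candidate-gene windows

A gene is a hit iff its body [start, end] intersects the *closed*
interval [pos − w, pos + w], w = 10 kb by default: "within 10 kb" is read
inclusively, so a gene whose nearest edge is exactly 10,000 bp away is
kept and 10,001 bp is not (both cases are pinned by tests).
Upstream/downstream labels are coordinate-based; strand is reported but
never affects inclusion. Coordinates are 1-based inclusive throughout
(VCF/GFF3 convention). The bundled annotation
(`synthetic_candidate_gff()`) is *synthetic*: real gene identifiers
placed at engineered offsets around the 14 reported SNP positions,
including the exact-boundary case, so the window logic is testable
without the reference genome.

## 6. RR-BLUP genomic prediction

`fit_rrblup()` fits $y = 1\mu + Zu + \varepsilon$,
$u \sim N(0, I\sigma^2_u)$, on the column-centered dosage matrix Z. The
restricted likelihood is profiled over $\lambda = \sigma^2_e/\sigma^2_u$
through the eigendecomposition of the intercept-projected kernel $ZZ'$
(a constant spectral offset separates the intercept direction from
genuine null-space directions), and optimized in $\log\lambda$ on
[−10, 10] to 1e-6; an optimum at the edge sets a boundary flag (the
noise-free limit legitimately drives $\lambda \to 0$). Marker effects are
$\hat u = Z'(ZZ' + \lambda I)^{-1}(y - 1\hat\mu)$ with the GLS intercept;
training GEBVs are algebraically identical to the GBLUP kernel solution,
which the tests assert at 1e-8, and a fixed-`lambda` mode exposes the
closed-form ridge solution for oracle comparison.

Cross-validation design choices:

- **Accuracy** is the Pearson correlation between predicted GEBVs and
  observed BLUPs of held-out lines — true breeding values are
  unobservable on real data; on simulated data the truth files allow the
  additional comparison.
- **Aggregation** is the mean over all fold-level correlations across
  repetitions (the natural reading of "average prediction accuracy").
- $\lambda$ is re-estimated inside every training partition; test
  phenotypes never inform shrinkage.
- **Top-k ranking** (`sweep_top_snps()`) follows the literal two-stage
  procedure: the GWAS ranking is computed once on the full population
  before cross-validation. This is knowingly optimistic (the ranking has
  seen the test lines' phenotypes); `refit_in_fold = TRUE` provides the
  leakage-free variant that re-ranks within each training fold, for
  methodological comparison.

## 7. Numerical choices and degenerate inputs

- Variance-component truncation at 0 with a warning (REML boundary).
- `single_marker_scan` p-values are clamped to
  [.Machine$double.xmin, 1]; degenerate (zero-residual-variance) markers
  get p = 1, never NA.
- BLUP equations: sparse Cholesky/LU with a 1e-8·n ridge floor;
  $\sigma^2_g \approx 0$ collapses BLUPs to the grand mean with a
  warning rather than dividing by zero.
- Phenotype export rounds to 0.1 day (field scoring precision); internal
  computation keeps full precision.
- Seeds: every stochastic function takes an explicit `seed`; derived
  per-stage seeds stay below 2^31. Identical seeds give bit-identical
  simulations, partitions, and pipeline outputs (checksummed manifest).

## 8. Problem sizes used by the test and acceptance suites

The suites are sized for a single desk CPU: panels of 200–379 lines with
800–5,000 markers; 20-replicate calibration/power simulations
(heritability recovery, family-wise error, planted-QTL detection); and a
fixed 379 × 5,000 oligogenic reference panel for the three accuracy-trend
experiments at 20 repetitions each. These sizes were chosen as the
smallest at which the tested inequalities have comfortable Monte Carlo
margins; all grids and repetition counts are arguments, so full-scale
runs (e.g. 100 repetitions, 134,785 markers) are a configuration change,
not a code change.

## 9. Known limitations

- The two multi-locus scans are *defined simplified algorithms* sharing
  the published models' ideas (iterative conditioning; bin- vs LD-based
  candidate control); numerical identity with the original GAPIT
  implementations is not claimed — behavioural parity (error control,
  power, multi-locus conditioning) is the tested contract.
- No kinship random effect in the scans (no MLM/EMMA step), no Bayesian
  alphabet predictors, no LD-interval gene search beyond the fixed
  window, no reference-panel imputation, no spatial trend correction.
- The simulator's uniform founder frequencies and equal-length
  chromosomes are idealizations; absolute accuracy values on simulated
  panels should be read as within-package comparisons, not forecasts for
  any particular field programme.
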