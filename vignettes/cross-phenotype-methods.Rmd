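---
title: "Methods: cross-phenotype analysis of GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-phenotype analysis of GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

pleioscan asks whether two complex traits — prototypically a case-control
osteoarthritis (OA) phenotype and a quantitative bone-mineral-density (BMD)
phenotype — share genetic aetiology, using nothing but per-variant GWAS
summary statistics and a block-structured LD reference. This vignette is the
package's own account of the models it fits, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the numerical
choices made where the design was open.

## Data model

Every analysis operates on harmonised summary statistics: per variant, an
effect size on the additive scale (log-odds for binary traits, per-SD units
for quantitative traits), its standard error, Z-score, p-value and sample
size. `harmonize_pair()` aligns a second study's alleles to the first's
(swaps negate effects, strand flips do not) and drops strand-ambiguous A/T
and C/G variants by default — the conservative standard when palindromic
orientation cannot be resolved. For binary traits the effective sample size
`4 / (1/n_cases + 1/n_controls)` is used wherever a single `n` is required,
which makes `z = beta * sqrt(n)` exact on the standardised-genotype scale.

LD enters through approximately independent blocks: a BED-like file of
half-open `[start, stop)` intervals, per-block signed correlation matrices,
and per-SNP LD scores `l_j = sum_k r^2_jk` (self included, so `l >= 1`).
Cross-block LD is defined to be exactly zero — that is what "approximately
independent" licenses, and it makes pruning, permutation and simulation
block-separable. No finite-sample bias correction is applied to the LD
scores because the reference LD is exact in the in-silico setting; for LD
estimated from a finite panel this is a documented limitation.

## Genetic correlation by LD score regression

For trait *t*, `E[chi2_j] = 1 + n_t h2_t l_j / m`; for the pair,
`E[z1_j z2_j] = c + sqrt(n1 n2) g l_j / m`, where `h2` is SNP heritability,
`g` the genetic covariance, and the free intercepts absorb confounding and
sample overlap respectively. Both are fitted by weighted least squares with
heteroskedasticity weights `1 / (2 (1 + n h2 l/m)^2)` (and the bivariate
analogue) iterated twice from an OLS start. The genetic correlation is
`rg = g / sqrt(h2_1 h2_2)`; standard errors come from a delete-one block
jackknife over 200 contiguous SNP blocks (the field's standard default,
configurable), with weights held fixed at the final fit, and the `rg`
p-value from the jackknife normal approximation. No constrained-intercept
mode is offered: sample overlap is modelled, not assumed away.

Two estimators of the overlap-induced null correlation `c` are provided: the
cross-trait LDSC intercept, and the Pearson correlation of Z-scores over
pruned (`r^2 < 0.2`) variants associated with neither trait
(`|z| < 1.96`), `z_correlation_overlap()`. The latter is the default scalar
fed to colocalisation and the cross-phenotype statistics, because it is
cheap, direct, and applies without fitting the regression.

Two details make this estimator consistent rather than merely conventional.
First, the pruning pass uses genomic-position order, not p-value order: the
retained set must not condition on the association statistics, or the
selection itself distorts the null Z distribution. Second, restricting a
bivariate normal to the square `|z| < 1.96` attenuates its correlation by a
known, correlation-dependent factor (about 0.78 near zero: a true
correlation of 0.3 yields a truncated Pearson value of only 0.235), so the
raw truncated correlation is mapped back through the exact
truncated-bivariate-normal relationship, computed by quadrature and
inverted numerically. The corrected estimator recovers a shared-sample
correlation of 0.3 to within 0.01 on a 50,000-SNP null panel; the raw value
is kept as an attribute for comparison with conventions that skip the
correction.

## Signal overlap with a permutation null

`prune_by_pvalue()` implements p-value-informed greedy pruning: visit
variants in ascending trait-1 p-value (ties broken by chromosome, position,
then id) and keep a variant iff its `r^2` with every kept variant in the
same block is at most 0.05. `permutation_overlap()` then cross-classifies
the pruned panel at ten descending thresholds (0.5 down to 5e-4), computes
the Pearson 2x2 chi-square (no continuity correction), and calibrates it by
randomly permuting the trait-2 p-values — one shared permutation stream
across thresholds, preserving their dependence.

The permutation p-value is one-sided for *enrichment*: with
`s = sign(observed - expected overlap) * chi2`, `p_perm =
(1 + #{s* >= s_obs}) / (n_perm + 1)`. The add-one estimator never returns
zero and the signed statistic makes the test exactly valid under the null
while refusing to call overlap *depletion* significant. Because the
permuted margins are fixed, the chi-square is a monotone function of the
overlap count, so the permutation answers exactly "how often does random
matching produce this much co-occurrence".

Two consequences worth knowing. First, for an enrichment-direction
observation with well-populated cells, `p_perm` converges to the one-sided
chi-square tail (half the two-sided p). Second, at extreme thresholds the
2x2 counts are tiny (at `P_t = 5e-4` on a 5,000-SNP panel the expected
overlap is below one variant) and the permutation p becomes strongly
conservative through discreteness; that is the correct behaviour of an
exact test, and the calibration experiment in the acceptance suite therefore
measures exact 5% calibration on the five thresholds whose expected cell
counts support it, and validity (no anti-conservatism) on all ten.

## Regional colocalisation

Per block, five hypotheses: no association (H0), one causal variant for one
trait only (H1/H2), one shared causal variant (H3), two distinct causal
variants (H4) — the single-causal-variant-per-trait frame. Per-SNP evidence
is the Wakefield approximate Bayes factor
`log ABF = 0.5 log(V/(V+W)) + z^2 W / (2(V+W))` with `V = se^2` and prior
effect variance `W = 0.04` (prior SD 0.2 on the log-odds / per-SD scale).
Priors `p1 = p2 = 1e-4`, `p12 = 1e-5` per SNP are the field-standard
defaults; every such constant is exposed in `coloc_priors()` because the
analysis this package reimplements does not print its own values.

Sample overlap enters where it matters most: the H3 joint Bayes factor is
the exact ratio of bivariate normal densities with null covariance
`[[1, c], [c, 1]]`, which factorises into the two univariate ABFs at
`c = 0` (an identity the tests hold to 1e-12). H1/H2/H4 use univariate
ABFs, a documented approximation. All per-hypothesis sums are assembled in
log-sum-exp arithmetic; the H4 sum over ordered distinct pairs is computed
as `exp(S1 + S2) - exp(S12)` in log space, clamped at `-Inf` when the
difference underflows, and is structurally zero for single-SNP regions.
Posteriors are reported per region, with regions flagged when the H3 or H4
posterior reaches 0.9, matching the reporting convention of the analysis
the package emulates.

## Cross-phenotype statistics and replication

`S_hom = (w' R^-1 z)^2 / (w' R^-1 w)` with `w = sqrt(n)` assumes one shared
effect and is chi-square(1) under the null; with `R = I` and
inverse-variance weights it *equals* the squared IVW meta-analysis Z, an
identity kept under test at 1e-10. `S_het` maximises the same statistic
over studies with `|z| > tau` on the grid `{0, 0.5, ..., 3}` (tau = 0 keeps
all studies). The original software's gamma approximation to the S_het null
is not recoverable from the text the package follows, so the null is Monte
Carlo — draws from `N(0, R)`, shared across variants since the null depends
only on `R`, the weights and the grid — with the add-one p estimator. This
is exact up to sampling error and, unlike an opaque approximation, directly
testable for calibration.

The study correlation matrix `R` is estimated exactly like the scalar
overlap (null-SNP Z correlation per pair), with an eigenvalue-floor repair
(floor 1e-6, rescale to unit diagonal) if the assembled matrix is not
positive definite; the repair is logged because it signals degenerate input.

Replication meta-analysis is fixed-effects IVW with METAL-style direction
strings; variants missing from a cohort contribute `?` and are excluded
from the direction-concordance sign test, which is a two-sided exact
binomial test (doubled smaller tail, capped at 1) of the count of variants
with identical direction in all k studies against `(1/2)^(k-1)`. Two-sided
because the emulated analysis does not state its sidedness, and two-sided
is the conservative choice.

## The synthetic-data generator

`simulate_polygenic_pair()` emulates the paired arcOGEN/GEFOS-style inputs:
a binary trait with 7,410 cases and 11,009 controls (effective n ~ 17,716)
and a quantitative trait with n = 31,800, genetic correlation `rg = 0.18`,
SNP heritabilities 0.25 and 0.30, and a small default sample-overlap
correlation of 0.05 (the consortia exclude known shared cohorts but residual
overlap is corrected for, so the default is small but non-zero). True
per-SNP effects are bivariate normal with variances `h2_i / m` and
covariance `rg sqrt(h2_1 h2_2) / m`; within each block the observed
Z-vector is `R lambda + eps` with `lambda = sqrt(n) beta`, per-trait noise
covariance `R` and cross-trait noise covariance `c R`. Sampling uses a
symmetric square root of `R` computed once per distinct block structure;
all randomness flows sequentially from one seed, so identical seeds give
bit-identical output (including file digests from `make_fixture()`).

The default LD is AR(1) within blocks of 50 SNPs with correlation cycling
over {0, 0.3, 0.6, 0.9} across blocks. The heterogeneity matters: it is
both the realistic emulation (real genomes mix recombination deserts and
hotspots) and a conditioning requirement — with identity LD all LD scores
equal 1 and the LDSC slope is unidentifiable, while with a single uniform
rho the LD scores cluster away from `l = 1` and the regression intercepts
become ill-conditioned extrapolations.

What the generator does *not* emulate: allele-frequency and imputation-info
structure (fields exist but are not simulated), minor-allele-dependent
power, population stratification, sex chromosomes, cross-block LD leakage,
and the million-SNP scale of real panels. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to real-data pathologies such as strand
misspecification at scale or confounding inflation.

## Problem sizes and numerical choices

The validation suite fixes its problem sizes as the package's own choices:
LDSC recovery uses 50 replicates of 20,000 SNPs at n = 20,000 (per-seed
Monte Carlo error ~ 0.06-0.09 per quantity, so 50-replicate means resolve
biases of a few hundredths); permutation calibration uses 500 null datasets
of 5,000 pruned SNPs with 2,000 permutations each; colocalisation recovery
uses 200 regions of 50 SNPs per hypothesis at non-centrality 8; S_het
calibration uses 50,000 shared null draws against 10,000 variants, sized so
that the Monte Carlo quantile error contributes well under a third of the
acceptance band.

Other numerical decisions: log-sum-exp throughout the colocalisation
arithmetic; `logdiffexp` clamps to `-Inf` rather than returning NaN when
rounding makes the H4 sum non-positive; pruning ties break
deterministically by (p, chromosome, position, id); the boundary variant of
a half-open block belongs to the downstream block; permutation and Monte
Carlo p-values use add-one estimators and so never return zero; pipeline
stages derive independent seeds from the top-level seed, which is why
disabling a downstream stage cannot change an upstream report.

## Known limitations

Single-causal-variant-per-trait colocalisation cannot represent allelic
heterogeneity; the overlap correction enters only the H3 joint term;
LDSC here fits mean sample sizes rather than per-SNP n; the generator's
binary-trait model is the standard effective-n Gaussian approximation, not
a liability-threshold simulation; and the null-SNP overlap estimators are
mildly attenuated when per-SNP polygenic signal is strong relative to the
panel size (visible at desk-scale m, negligible at real-GWAS m).
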