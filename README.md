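# pleioscan

Cross-phenotype pleiotropy analysis of GWAS summary statistics.

`pleioscan` asks whether two complex traits share genetic aetiology — the
prototype being osteoarthritis (a binary, case-control phenotype) and bone
mineral density (a quantitative one) — using only per-variant summary
statistics and a block-structured LD reference. It is aimed at statistical
geneticists who have two association studies' summary files and want the
standard cross-trait toolkit in one tested, seeded, scriptable package:

- **Harmonisation** of summary-statistics tables to a common allele frame
  (`read_sumstats()`, `harmonize_pair()`), with strand-ambiguous variants
  dropped by default.
- **Genetic correlation** by bivariate LD score regression: for LD score
  `l_j`, the fits are `E[chi2_j] = 1 + n h2 l_j / m` and
  `E[z_1j z_2j] = c + sqrt(n1 n2) g l_j / m`, so the slope measures SNP
  heritability h2 / genetic covariance g and the free intercept `c` absorbs
  sample overlap; `rg = g / sqrt(h2_1 h2_2)` with block-jackknife standard
  errors (`bivariate_ldsc()`, `z_correlation_overlap()`).
- **Signal overlap**: p-value-informed greedy LD pruning (r² ≤ 0.05),
  2×2 chi-square tests of co-occurrence below ten p-value thresholds, and a
  one-sided enrichment permutation null with the add-one estimator
  `p_perm = (1 + #{s* ≥ s_obs}) / (n_perm + 1)`
  (`prune_by_pvalue()`, `permutation_overlap()`).
- **Regional Bayesian colocalisation** over approximately independent LD
  blocks: posterior probabilities for H0 (no signal), H1/H2 (one trait
  only), H3 (one shared causal variant), H4 (two distinct causal variants),
  from Wakefield log approximate Bayes factors
  `0.5 log(V/(V+W)) + z² W / (2(V+W))`, with sample overlap entering the H3
  joint Bayes factor (`region_posteriors()`, `genome_coloc_scan()`).
- **Cross-phenotype association statistics** for correlated studies,
  `S_hom = (w'R⁻¹z)² / (w'R⁻¹w)` and the truncation-maximised `S_het` with
  a Monte Carlo null (`s_hom()`, `s_het()`, `cpassoc_scan()`).
- **Replication meta-analysis**: fixed-effects inverse-variance pooling
  with METAL-style direction strings and an exact binomial
  direction-of-effect sign test (`ivw_meta()`, `meta_scan()`,
  `sign_test()`).
- A **synthetic-data generator** with known truth — block AR(1) LD,
  bivariate polygenic effects with tunable rg, regional causal
  configurations matching H0–H4, and correlated null noise from shared
  samples — so the whole pipeline is testable end-to-end without
  access-controlled consortium data (`simulate_polygenic_pair()`,
  `simulate_coloc_regions()`, `make_fixture()`).
- A **pipeline driver** (`run_pipeline()`, `pipeline_config()`) writing
  per-stage TSV/JSON reports and a manifest, byte-identical for a fixed
  seed. A thin command-line wrapper lives at
  `inst/scripts/run_pipeline.R`.

## Worked example

Simulate an OA-like / BMD-like study pair at its default study conditions
(7,410 cases / 11,009 controls vs n = 31,800, true rg = 0.18, SNP
heritabilities 0.25 / 0.30), then estimate the genetic correlation and the
threshold overlap:

```r
library(pleioscan)

cfg <- sim_config(m_snps = 10000, seed = 42)
sim <- simulate_polygenic_pair(cfg)

fit <- bivariate_ldsc(sim$a, sim$b, ld_scores(sim$ld))
fit
#> Bivariate LD score regression: OA_like vs BMD_like
#>   h2_1 = 0.2659 (SE 0.0435)   h2_2 = 0.3788 (SE 0.0502)
#>   gcov = 0.0964 (SE 0.0406)   rg = 0.3039 (SE 0.1242), p = 0.0144
#>   cross-trait intercept (sample overlap) = -0.1072 (SE 0.1257)
#>   10000 SNPs, 200 jackknife blocks

ov <- overlap_analysis(sim$a, sim$b, sim$ld, sim$blocks,
                       config = overlap_config(n_perm = 10000, seed = 1))
tibble::as_tibble(ov)[, c("threshold", "n_overlap", "p_chi2", "p_perm")]
#> # A tibble: 10 × 4
#>    threshold n_overlap   p_chi2    p_perm
#>  1    0.5         2009 8.90e- 1 0.453
#>  2    0.1          354 6.50e- 3 0.00410
#>  3    0.05         183 6.34e- 4 0.000900
#>  ...
#>  9    0.001         20 3.49e-15 0.0001000
#> 10    0.0005        14 6.91e-12 0.0001000
```

Read: the estimated genetic correlation is 0.30 (true value 0.18, within
one standard error at this panel size) and is nominally significant
(p = 0.014); variants associated with both traits co-occur far in excess of
chance at stringent thresholds — at P_t = 0.001, 20 pruned variants fall
below the threshold in both traits and no permutation out of 10,000
matched it (`p_perm = 1/10001`). `tidy()`, `glance()`, `autoplot()` and
`plot_qq()` work on the fitted objects and result tables; colocalisation
and the cross-phenotype statistics follow the same data-frame-in,
tibble-out pattern (`genome_coloc_scan(sim$a, sim$b, sim$blocks)`).

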