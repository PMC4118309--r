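# cnpassoc

Association testing for common copy number polymorphisms (CNPs) measured on
SNP genotyping arrays, with a log-scale quantitative trait such as serum
uric acid.

Common deletions near trait genes are hard to study with off-the-shelf GWAS
tooling: copy number must first be inferred from noisy marker-level
intensities (log R ratio, B allele frequency), technical artifacts such as
GC-correlated *genomic waves* and chemistry-plate batch effects dominate
small dosage signals, and effect sizes on a log-transformed trait are most
naturally reported as a percentage change per copy. `cnpassoc` implements
the whole path from intensities to association statistics:

1. **Wave correction** — per-sample least-squares residualization of the
   log R ratio (LRR) on a windowed local-GC covariate, recentered to
   preserve each sample's mean (`windowed_gc()`, `select_window()`,
   `correct_waves()`).
2. **Segmentation** — a six-state hidden Markov model (copy numbers 0–4
   plus a copy-neutral ROH state) with distance-dependent transitions and
   joint LRR/BAF emissions, decoded per sample by the Viterbi algorithm;
   calls with fewer than 10 markers are dropped (`hmm_params()`,
   `viterbi_segments()`, `filter_min_markers()`).
3. **Sample QC** — exclusion when lag-10 autocorrelation > 0.03, MAD >
   0.32 or more than 100 CNV calls; genotype-cluster SNR reported as a
   diagnostic (`qc_metrics()`, `apply_qc()`, `burden_summary()`).
4. **CNP regions** — disjoint intervals from the union of all CNV
   breakpoints, a cohort copy-number matrix, a ≥ 1% carrier-frequency
   filter, and merging of adjacent intervals into loci
   (`breakpoint_union()`, `build_cn_matrix()`, `frequency_filter()`,
   `group_loci()`).
5. **Mixture genotyping** — region-averaged LRRs follow a 3-component
   normal mixture induced by copy numbers 0/1/2; a conjugate Gibbs sampler
   approximates the posterior and each subject gets the
   maximum-a-posteriori component (`region_mean_lrr()`, `gibbs_mixture()`,
   `map_assign()`).
6. **Trait association** — seasonal lowess-style adjustment of the log
   trait, then linear mixed models (ML, random plate intercept) comparing a
   covariate-only baseline against models with copy number and its sex
   interaction by 1- or 2-df likelihood-ratio tests; effects reported as
   `100·(e^β − 1)` percent per copy (`seasonal_adjust()`, `fit_baseline()`,
   `fit_cnp()`, `pct_change()`, `genome_scan()`, `conditional_fit()`,
   `haplotype_association()`, `binary_outcome_fit()`).
7. **Surrogate imputation** — missing genotype calls at an in-CNP SNP as a
   surrogate for homozygous deletion, with sensitivity/specificity
   evaluation and quantification of the attenuation bias the surrogate
   induces (`surrogate_indicator()`, `concordance()`,
   `attenuation_experiment()`).

Because the motivating cohort data are access-restricted, the package ships
a first-class synthetic-cohort generator (`sim_config()`, `cnp_spec()`,
`trait_spec()`, `simulate_marker_map()`, `simulate_cohort()`) with known
ground truth: Hardy–Weinberg deletion haplotypes at two negatively linked
loci, genomic waves, plate effects, seasonal trait trends and sex-specific
multiplicative dosage effects. Every pipeline stage is tested against it.

## Worked example

```r
library(cnpassoc)

locus <- cnp_spec("chr1", 4e4, 6e4, deletion_allele_freq = 0.24)
cfg <- sim_config(
  n_subjects = 2000, chrom_lengths = c(chr1 = 1.2e5), marker_spacing = 1000,
  cnp_loci = list(locus), wave_amplitude = 0.02, n_plates = 24,
  trait_model = trait_spec(cn_effect_female = -log(1.0493),
                           cn_effect_male  = -log(1.0136)),
  seed = 1)
map    <- simulate_marker_map(cfg)
cohort <- simulate_cohort(map, cfg)

avg <- region_mean_lrr(cohort$intensity, locus)
fit <- gibbs_mixture(avg$mean_lrr, n_iter = 1500, burn_in = 500, seed = 2)
tidy(fit)
#> # A tibble: 3 × 5
#>   component    cn    mean     sd weight
#>       <int> <int>   <dbl>  <dbl>  <dbl>
#> 1         1     0 -1.98   0.0550 0.0616
#> 2         2     1 -0.530  0.0457 0.359
#> 3         3     2  0.0221 0.0477 0.579

pheno <- seasonal_adjust(cohort$phenotype)
assoc <- fit_cnp(pheno, map_assign(fit), sex_interaction = TRUE)
pct_change(assoc$effects$beta, assoc$effects$se, per_deleted = TRUE)
#> # A tibble: 2 × 5
#>     beta     se   p2.5   p50 p97.5
#>    <dbl>  <dbl>  <dbl> <dbl> <dbl>
#> 1 0.0430 0.0100  2.36   4.39  6.46
#> 2 0.0159 0.0116 -0.679  1.60  3.93
```

The mixture means sit at the expected LRR levels for copy numbers 0/1/2 and
the component weights match the Hardy–Weinberg frequencies of a deletion
allele at frequency 0.24 (0.058 / 0.365 / 0.578). The final table gives the
percentage change of the trait per *deleted* copy with 2.5/50/97.5
percentiles: women ≈ +4.4% per deleted copy and men ≈ +1.6% here, against
injected truths of 4.93% and 1.36% (the 2-df interaction LRT in
`glance(assoc)` gives chi-square 20.2, p = 4.1e-05). At the full cohort size (n = 8411) the
estimates concentrate tightly around the injected values.

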