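---
title: "Copy-number polymorphism genotyping and trait association: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number polymorphism genotyping and trait association: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnpassoc)
```

This vignette is the package's account of its statistical machinery: the
observation model linking latent copy number to array intensities, the
hidden Markov model and Bayesian mixture used to infer copy number, the
mixed models used to test it against a log-scale quantitative trait, and
the design decisions taken where several reasonable choices existed. It
states no empirical result beyond what the test suite and
`scripts/acceptance.R` compute.

## The observation model

A SNP array reports two summaries per marker. The **log R ratio (LRR)** is
log-scale total fluorescence relative to a diploid reference; it shifts
down with deletions and up with duplications, but compressed relative to
the ideal `log2(c/2)` because of probe saturation and normalization. The
**B allele frequency (BAF)** at a SNP estimates the relative abundance of
the B allele and clusters at `b/c` for a genotype with `b` B alleles out of
`c` copies; with zero copies there is no signal and BAF is uniform noise.

The synthetic-cohort generator (`simulate_cohort()`) is the generative
counterpart of this model:

```
LRR[i, j] = mu(CN[i, j]) + a[i] * wave(j) + plate[i] + e[i, j]
```

* `mu(CN)` defaults to `(-2.0, -0.55, 0.0, 0.35, 0.65)` for copy numbers
  0–4 — a deliberately compressed response typical of array data. No
  canonical published values exist for these emissions, so they are package
  defaults, configurable through `sim_config(lrr_mu = ...)` and
  `hmm_params(lrr_mean = ...)`.
* `wave(j)` is a genomic wave: a standardized mix of the 50-kb-smoothed
  local GC content and a low-frequency sinusoid along the chromosome. The
  per-subject amplitude `a[i]` is log-normal (sdlog 0.5) around
  `wave_amplitude`, so a minority of samples are markedly wavier — exactly
  the samples that per-sample quality control exists to catch.
  `sim_config(n_qc_violators = k)` additionally forces `k` subjects to an
  extreme amplitude as deliberate QC fixtures.
* `plate[i]` is a normal chemistry-plate intercept (LRR scale) shared by
  all samples on a plate, and `e` is i.i.d. marker noise (`lrr_sd`,
  default 0.2).

BAF at SNPs is drawn from truncated normals (sd `baf_sd = 0.03`) at the
genotype-conditional centers `b/c`, with `b ~ Binomial(c, p_B)` and a
uniform draw at copy number zero.

**Copy number itself is haplotype-level.** Each CNP locus
(`cnp_spec()`) carries a deletion allele at frequency `f`; each haplotype
carries 0 or 1 copies, so subject copy number is 0/1/2 under
Hardy–Weinberg. Two loci can be *linked with repulsion* `r ∈ [-1, 0]`: the
joint haplotype distribution has covariance `r·sqrt(f1(1-f1)f2(1-f2))`,
clipped at zero. With full repulsion (`r = -1`) and allele frequencies
0.68 / 0.24 the generator reproduces the empirical regime that motivates
this structure: subject-level copy numbers at the two loci have a Spearman
correlation near −0.8, homozygous deletion rates near 46% and 6%, and no
subject is homozygously deleted at both loci. These are the package
defaults for the two-locus experiments in the tests.

What the generator does **not** emulate: allele-specific probe effects,
population stratification and admixture, family relatedness, mosaic
(fractional) copy number, and the long-tailed non-Gaussian noise of real
arrays. Passing tests therefore demonstrate correctness of the inference
machinery under a faithful but idealized observation model, not performance
on any real cohort.

## Wave correction

Genomic waves are removed by per-sample least squares: LRR is residualized
on the windowed mean GC (`windowed_gc()`, total window `w`, edge windows
truncated) and recentered to the sample's original mean, so the sample-level
intensity level — which carries no copy-number information but stabilizes
downstream summaries — is preserved exactly. A single window is chosen by
maximizing the median (across samples) squared correlation between LRR and
the GC covariate over a candidate grid (default 10 kb / 50 kb / 250 kb /
1 Mb), ties to the smallest window. A single-window linear residualization
was chosen over a multi-resolution search because correction is
preprocessing here; the segmentation and association stages are the
scientific core, and the tests verify the two properties that matter for
them — the lag-10 autocorrelation drops, and a deletion's LRR contrast
against its flanks is preserved within 10%. If the GC covariate is
constant the correction is a flagged no-op.

## The six-state HMM

Segmentation uses a hidden chain over `CN0, CN1, CN2, CN2-ROH, CN3, CN4` —
six states, five distinct copy numbers. The ROH state exists because long
runs of homozygosity mimic the BAF signature of a deletion (no
heterozygotes) at normal LRR; giving that configuration its own
copy-number-2 state prevents spurious deletion calls. Emissions are the
Gaussian LRR density plus, at SNPs, an equal-weight mixture of truncated
normals at the state's permitted BAF centers (uniform for CN0). Markers
with missing LRR are skipped entirely. Transitions are distance-dependent:

```
P(stay) = 1 - epsilon * (1 - exp(-d / D))
```

with the off-diagonal mass split proportionally to the stationary
distribution. Defaults `epsilon = 0.01`, `D = 100 kb` make state changes
rare and increasingly likely across large gaps; both are configurable and
no claim of optimality is made. Decoding is per-sample Viterbi (samples are
independent); the test suite checks the decoder against exhaustive
enumeration of all `6^m` paths on short instances, and forward–backward
posteriors against the sum-to-one invariant at `1e-10`. Calls supported by
fewer than 10 markers are removed — short calls at array noise levels are
unreliable — with the boundary inclusive: exactly 10 markers is kept.

Coordinates are 1-based closed on marker positions. Chromosome X/Y
handling and joint multi-sample calling are out of scope.

## Sample QC

Three per-sample statistics on the genome-ordered autosomal LRR series:
lag-10 autocorrelation (biased normalization, chromosomes concatenated in
map order), the normal-consistent MAD (`1.4826 × median |x − median|`), and
the CNV call count. Exclusion thresholds 0.03 / 0.32 / 100 are adopted
verbatim, all strict (`>`): a sample exactly at a threshold is retained.
Whether the 0.32 MAD cutoff was originally meant for the raw or the
normal-consistent MAD is ambiguous; this package applies it to the
normal-consistent MAD (the R default) and exposes it as an argument. The
genotype-cluster signal-to-noise ratio (between-cluster over mean
within-cluster variance of the allelic contrast) is reported as an array
quality diagnostic only and never used for exclusion.

One sizing note, relevant to anyone testing with toy data: the null
standard deviation of a lag-10 autocorrelation on `m` markers is about
`1/sqrt(m)`, so the 0.03 cutoff is only meaningful on dense, array-scale
series (hundreds of thousands of markers or more). The QC retention tests
consequently use a 30-Mb, 30,000-marker synthetic chromosome.

## Disjoint intervals and the copy-number matrix

All CNV start/end coordinates across the cohort cut the covered territory
into maximal disjoint intervals, each fully inside or outside every CNV,
so each subject's copy number is constant ("unambiguous") within an
interval; intervals with no marker are dropped. The implementation uses
`IRanges::disjoin()`, and the tests hold it to a per-basepair brute-force
oracle. The cohort matrix defaults to 2 wherever no CNV overlaps. A
partial overlap, or two same-subject calls of different copy number on one
interval, is an input-contract violation and raises an error rather than
being resolved silently.

An interval is a CNP when at least 1% of subjects carry a non-diploid copy
number there (both deletions and duplications count as carriers); the
boundary is `>= 0.01` exactly. Adjacent retained intervals merge into loci
when **no marker** lies strictly between them — adjacency is
marker-relative, not base-pair-relative, because the interval grid itself
only exists at marker resolution.

## Bayesian mixture genotyping

At a CNP locus the per-subject *region-averaged* LRR compresses marker
noise by `1/sqrt(#markers)`, leaving a clean three-component normal mixture
indexed by copy number 0/1/2. The Gibbs sampler uses fully conjugate
updates (labels; means with Normal priors; variances with
Inverse-Gamma(2, 0.05); weights with Dirichlet(1,1,1)) and resolves label
switching by relabeling components in ascending mean *every sweep* rather
than post hoc. Prior means default to the empirical 1/6, 1/2, 5/6
quantiles with prior sd 1 — weakly informative; the chain is
**initialized at 1-D k-means centers** because the homozygous-deletion
component can be rare (a few percent) and far from the bulk, where quantile
initialization risks an absorbing local mode that splits the diploid
cluster instead. Membership probabilities are Rao–Blackwellized averages of
conditional responsibilities over post-burn-in sweeps; the MAP label (ties
toward the lower copy number) is the genotype. A fit where a component is
empty in more than half the sweeps is flagged degenerate but still
returned.

`k` is fixed at 3: the loci this pipeline targets are deletion
polymorphisms. Duplication-bearing loci would need `k > 3` and are out of
scope. Sampler defaults are 4000 sweeps with 1000 burn-in; the acceptance
experiments use 1500/500, which is ample here — with separations of 5+
within-component standard deviations the chain forgets its initialization
within tens of sweeps, and the label-stability test (20 independent chains,
posterior means agreeing within 0.02) confirms it.

## Trait association

The trait is strictly positive and right-skewed, so all modeling is on
`log(trait)`, and slopes `β` are reported as `100·(e^β − 1)` percent change
per copy (`pct_change()`, with `per_deleted = TRUE` flipping the sign
convention to "per deleted copy"). Interval estimates are Wald limits on
the log scale transformed to percent, written as a (2.5, 50, 97.5)
percentile triple; the transform is exactly invertible
(`β = log(1 + p50/100)`).

**Seasonal adjustment.** Analyte concentrations drift seasonally, and draw
dates can confound batch structure. Within each sex, `log(trait)` is
smoothed against draw date by a tricube-weighted local linear regression
and the residual (plus the sex-specific grand mean) is carried forward.
The "span 110" of the original description is ambiguous (days? neighbor
count? software-specific?); this package interprets it as a **110-day
total window** (55-day kernel half-width), which removes an annual
sinusoid nearly completely while leaving white noise essentially untouched
— the property the tests assert. The smoother is evaluated on a ~200-point
date grid and linearly interpolated; sparse windows fall back to the five
nearest points. Strata with fewer than ten subjects are passed through
unadjusted with a warning.

**Mixed models.** The baseline model has fixed effects for study center,
age, log BMI, sex, and age×sex and log-BMI×sex interactions, plus a random
chemistry-plate intercept, fitted by **maximum likelihood** (not REML) so
that likelihood-ratio tests between nested fixed-effect models are valid.
The CNP model adds copy number as a continuous 0–4 covariate — either one
slope (1-df LRT) or separate female/male slopes (`cn_female`, `cn_male`;
2-df LRT). Sex-specific slopes come from the single interaction model, not
stratified fits; stratified fits remain available as a diagnostic by
subsetting. With a single plate the random effect is degenerate and the
model is fitted by OLS, which the tests pin to the closed-form `lm`
limit. A singular baseline design raises an error naming the collinear
columns; in *extended* models an aliased covariate (e.g. a perfectly
tagging SNP dosage) is instead dropped, so the LRT correctly reports no
additional signal.

**Genome scan.** `fit_cnp()` per frequency-filtered interval, with
`-log10 p`, a Bonferroni flag at `0.05 / #intervals`, and Manhattan/QQ
plots. Adjacent intervals carry correlated statistics, so Bonferroni is
conservative; no permutation scheme is implemented, matching the stated
analysis plan of the original study design.

**Conditional and haplotype models.** SNP dosages (B-allele counts 0/1/2,
treated as continuous) can enter both baseline and extended models to test
independence of the CNP signal from nearby SNPs. With phased input
(phasing itself is an upstream input, not implemented here), subjects are
stratified by their unordered SNP-haplotype pair and the trait is
regressed on the unordered CNP-haplotype-pair category within each stratum
(reference = most common pair; LRT with categories−1 df; rare categories
and small strata excluded). The diploid convention — each haplotype
carries one copy — makes subject copy number the sum of its two haplotype
copies, which the generator guarantees and a test asserts.

**Binary outcomes.** Logistic regression with the same covariates, plate
as a *fixed* effect (no random-effect logistic model is attempted), giving
an odds ratio per copy; adding the adjusted log trait as a covariate
assesses mediation — an outcome generated solely through the trait should
show an attenuated, near-null copy-number OR once the trait is in the
model.

## Surrogate imputation of deletion genotypes

When raw intensities are unavailable (e.g. an older platform), a missing
genotype call at a SNP inside the CNP serves as a surrogate for homozygous
deletion: zero copies leave nothing to hybridize. `concordance()`
quantifies the surrogate against truth — sensitivity on copy-number-0
subjects, specificity on copy-number-2 subjects, hemizygous subjects
tabulated but outside both rates, since canonical biallelic clusters are
the natural reference class. The worked example in the tests reproduces
the 6-of-8 arithmetic: sensitivity 0.75, specificity 1.

Because the unflagged class is contaminated with hemizygous and undetected
homozygous deletions, regressing on the surrogate attenuates the effect
toward zero. `attenuation_experiment()` measures this directly: the
true-copy-number slope is rescaled to the homozygous-deletion (two-copy)
contrast so the two estimates share a coding scale, and their ratio is the
attenuation factor. The monotonicity of attenuation in sensitivity is
tested at deletion allele frequency 0.68, where homozygous deletions are
common enough (≈46% of subjects) for sensitivity to matter; at frequency
0.24 the effect of varying sensitivity on the ratio is a fraction of a
percent — real, but far below simulation noise at any reasonable cohort
size.

## Problem sizes and numerical choices

* Injection-recovery experiments: n = 8411 subjects, 100 plates, a 120-kb
  chromosome at 1-kb marker spacing (~20 markers in the CNP), 10 seeds,
  Gibbs 1500/500. Chosen to match the cohort-scale design (about 85
  subjects per plate) while the simulated chromosome covers only the
  neighborhood the experiment needs.
* Type-I error of the 2-df interaction LRT: 500 null replicates at n = 500
  on a fixed covariate design, rejection rate required in [0.03, 0.07].
* Viterbi-vs-enumeration: 200 instances with 2–8 markers (the exhaustive
  oracle enumerates up to 6^8 paths).
* Tolerances: forward–backward normalization at 1e-10; Viterbi/enumeration
  score agreement at 1e-10; wave-correction idempotence at 1e-6 RMS;
  subject-mean preservation at 1e-8.
* Ties: MAP genotype ties break toward the lower copy number; window
  selection ties toward the smaller window; mixture components are ordered
  by ascending mean.
* Degenerate inputs: constant LRR series return autocorrelation 0 with a
  warning; a constant GC covariate makes wave correction a flagged no-op;
  an all-identical mixture input yields a flagged degenerate fit; a
  monomorphic copy-number vector or outcome is an error.

## Known limitations

Autosomes only; no family structure or kinship random effects; no `k > 3`
mixtures (duplication CNPs); no multi-resolution wave model; no
permutation-based multiple-testing correction; phasing is consumed, not
performed. The synthetic cohort is the validation substrate — conclusions
about real-array performance require real intensities.
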