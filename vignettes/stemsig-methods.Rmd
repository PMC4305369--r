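---
title: "Methods: multi-cell-type microarray signature analysis with stemsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-cell-type microarray signature analysis with stemsig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemsig)
```

# Scope

stemsig re-implements, as a tested pipeline, the analysis chain used in
single-channel microarray studies that compare several cell types — in the
motivating design, five chicken cell populations (embryonic stem cells cES,
blastodermal cells cBC, primordial germ cells PGC, and two somatic
references, embryonic fibroblasts CEF and the monocytic line BM2), each
hybridized in triplicate on a ~44k-probe array. The chain is:

1. probe-level input (GenePix-style `.gpr` scans, GAL-style annotation);
2. normexp background correction, log2, within-array lowess, between-array
   average-quantile normalization, duplicate-spot averaging;
3. per-probe group means, empirical-Bayes moderated t for all pairwise
   contrasts, Benjamini–Hochberg correction, dual-threshold U/D/n calls;
4. FC-score signature extraction (cell-type-specific, shared-stem,
   germ-cell lists, Venn partitions);
5. cross-platform "virtual array" integration with ANOVA ranking, PCA and
   hierarchical clustering;
6. comparative ΔΔCt qPCR quantification and microarray concordance.

Every stage can be exercised against planted ground truth from the
synthetic-data generator, which is itself first-class, tested code.

# The intensity model and preprocessing

## Normexp background correction

Observed spot intensity is modelled as $X = S + B$ with signal
$S \sim \mathrm{Exp}(\alpha)$ and background
$B \sim N(\mu, \sigma^2)$ (all in scanner units). `estimate_normexp()`
fits $(\mu, \sigma, \alpha)$ per array by maximum likelihood of the
convolution density, and `normexp_correct()` returns
$E[S \mid X = x]$, which is strictly positive and increasing in $x$ — so
no probe is lost to a non-positive background-subtracted value.

Numerical choices:

* The likelihood is optimized over $(\mu, \log\sigma, \log\alpha)$ with
  box constraints around the starting values; the box keeps the optimizer
  away from the $\sigma \to 0$ corner that the likelihood can favour when
  the signal distribution deviates from exponential.
* Starting values come from the method of moments
  ($E X = \mu + \alpha$, $\operatorname{Var} X = \sigma^2 + \alpha^2$,
  third central moment $2\alpha^3$); because a heavy right tail of truly
  differential probes can break the third-moment identity, a robust
  alternative start (background statistics from the low-intensity tail) is
  also evaluated and the better-likelihood start is used.
* $E[S \mid x]$ is evaluated through the inverse Mills ratio in log space;
  for standardized residuals below $-8$ an asymptotic expansion replaces
  the direct formula, which otherwise cancels catastrophically.

## Within-array lowess

For single-channel data the package defines the M-A construction against a
pseudo-reference: $M_{ij} = v_{ij} - \bar v_i$, smoothed against
$A_i = \bar v_i$ (the probe's mean log2 intensity across arrays), with a
robust lowess (span 0.3, 3 robustifying iterations); the fitted trend is
subtracted. Two design points deserve a note:

* The abscissa is the across-array mean, not the array's own value.
  Using the array's own intensity couples the smoother's input with the
  deviation being smoothed (an errors-in-variables artifact) and places
  truly differential probes at the extreme of the axis where they dominate
  the local fit; both effects visibly shrink planted fold changes in
  simulation. Against the across-array mean, differential probes stay
  spread over the axis and the robust smoother ignores them.
* Correcting the arrays changes the pseudo-reference, so the correction is
  iterated (2 passes by default, the cyclic-loess convention). One pass
  leaves the share of a distortion that leaked into the reference in
  place; with two passes the residual trend of a planted quadratic
  distortion drops from ~0.07 to ~0.02 log2.

With two arrays the construction reduces to classic MA-plot lowess up to
the factor $\tfrac12$ in $M$.

## Quantile normalization and duplicate spots

`quantile_between_arrays()` maps each column's rank-$k$ value to the mean
of rank-$k$ values across arrays; ties receive the mean of the reference
values their span covers, which makes the operator well defined and
idempotent. `average_duplicates()` replaces duplicate spot rows by their
arithmetic mean, preserving first-occurrence order. The full chain order is
background-correct → log2 → lowess → quantile → duplicate averaging, the
standard single-channel convention.

A known, deliberate property: with asymmetric differential expression
(more genes elevated in some groups than others) average-quantile
normalization compresses the top tail and hence slightly attenuates large
fold changes — an inherent cost of forcing identical distributions, shared
with every pipeline built on this normalization.

# Differential expression

`fit_group_model()` computes per-probe group means and the pooled
within-group variance $s_g^2$ with $d_g = N - k$ degrees of freedom.
`estimate_prior()` fits the scaled-inverse-$\chi^2$ variance prior
$(d_0, s_0^2)$ by matching the first two moments of $\log s_g^2$
(trigamma matching, Newton inversion of the trigamma function); zero excess
dispersion yields the $d_0 = \infty$ sentinel, and literally constant
variances return the common value as $s_0^2$. `moderated_t()` shrinks
$\tilde s^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and refers
$t = \widehat{\Delta}/(\tilde s \sqrt{1/n_a + 1/n_b})$ to a t distribution
on $d_0 + d_g$ df (normal when $d_0 = \infty$). With $d_0 = 0$ this is
exactly the ordinary pooled two-sample t, which the tests exploit as an
oracle; the full pipeline is cross-checked against an independent
empirical-Bayes implementation.

Calls use the dual threshold of the study design: adjusted p below 0.05
*and* |log2FC| above 2, strict inequalities by default (the inclusive
variant is a switch). Benjamini–Hochberg adjustment is applied per contrast
by default; a pooled mode across all contrasts exists behind a flag, since
published descriptions often leave this choice implicit.

# FC-score signatures

For a reference cell type, every probe with at least one non-`n` call
carries an ordered U/D/n string over the other groups (design-table order)
and the **FC score**: the sum of its log2 fold changes over the contrasts
where differential expression was called. In a five-type design at the
|log2FC| ≥ 2 call threshold, a probe up-regulated against all four other
types scores at least +8 — the signature threshold.

* `select_specific()`: probes U against every other group.
* `select_shared_stem()`: annotated genes with FC score ≤ −8 in *each*
  somatic reference profile (CEF and BM2), i.e. genes strongly lower in
  both somatic types than elsewhere; the intersection operationalizes the
  shared stem/pluripotency signature. The direction convention (score of
  the somatic profiles, not of the stem profiles) is the reading that
  reproduces the construction's intent; both the threshold and the
  reference sets are arguments.
* `select_germ()`: annotated genes with FC score ≥ +8 in the germ-analog
  (PGC-like) profile, ranked by descending score. In this design the germ
  signature *is* the germ-analog group's specific profile; the generator
  therefore plants `germ` as that group's elevated class rather than
  duplicating it with a separate "specific" class whose members would be
  indistinguishable.
* Unannotated probes are retained in all probe-level outputs but excluded
  from gene-level signatures, mirroring practice on a genome whose
  annotation is incomplete.

A sharpness note, relevant to interpreting recovery claims: a shared-stem
gene can be called in at most three of the four contrasts of a somatic
profile (the two somatic types do not differ at it), so at a planted effect
of 3 log2 its expected score is −9 against a threshold of −8. At residual
sd 0.3 and triplicates, the score's sampling sd is ≈ 0.6, so even an ideal
estimator misses ≈ 9% of shared-stem genes jointly across the two somatic
profiles; at sd 0.2 the miss rate drops to ≈ 1%. Sensitivity targets of
0.95 for this class are therefore attainable at sd 0.2 but not at sd 0.3,
regardless of implementation quality; the test suite asserts the
expression-level recovery property at sd 0.2 and documents the array-level
behaviour at sd 0.3.

# Cross-dataset integration

`collapse_probes_to_genes()` averages probes per (upper-cased) symbol —
the same mean rule as duplicate spots. `build_virtual_array()` restricts
datasets to their common symbols, quantile-normalizes all samples to one
reference distribution, then centers each gene within each dataset at its
dataset median. The centering removes additive platform offsets exactly (a
constant shift of one dataset provably leaves the downstream tree
unchanged) while preserving within-dataset group contrasts; it is the
minimal batch treatment sufficient for cross-platform co-clustering of
biologically matched groups, and the harmonization step is pluggable.

`anova_rank()` computes per-gene one-way F across biological groups by
vectorized sums of squares (ranked by ascending p, ties by descending F,
then symbol — deterministic), with `top_ranked()` extracting the heatmap
matrix (the study convention keeps the first 1000 ranked genes).
`pca_scores()` is row-centered PCA over samples with per-group replicate
barycenters; `hierarchical_tree()` clusters samples on
1 − Pearson correlation with average linkage (samples processed in sorted
id order for deterministic ties) and exports newick.

# qPCR validation

`relative_quantification()` implements the comparative ΔΔCt method with
amplification efficiency fixed at 2: ΔCt against the internal-control gene
per sample, ΔΔCt against the arithmetic-mean ΔCt of the calibrator group,
RQ = 2^(−ΔΔCt). By construction the calibrator group's geometric-mean RQ
is exactly 1 per gene, and RQ is invariant to adding a constant to all Ct
values of a sample. `concordance()` scores sign agreement between qPCR
log2 RQ and microarray log2FC over shared genes. Technical replicates are
expected to be averaged to one Ct per sample and gene before input.

# The synthetic-data generator

`generate_experiment()` emulates the motivating study's structure: 5
groups × 3 replicates; tens of thousands of probes of which a configurable
fraction (default 0.578) carry a gene symbol; duplicate spots (default 10%
of probes printed twice, identical layout on every array); exponential
signal plus normal background; and a smooth array-specific
intensity-dependent bias. Planted classes — per-type specific, shared-stem
(elevated in all three stem-analog groups), germ (elevated in the
germ-analog group) — default to 40/88/60 at desk scale and to the
published list sizes (511/666/37/110/182 specific, 88 shared) at full
array scale.

Generative details and the reasoning behind them:

* Each probe's baseline signal is drawn once from Exp(mean
  `signal_alpha`, default 800), so the across-probe signal marginal
  matches the normexp model and parameter recovery is a fair test. Fold
  effects and per-spot residual noise (sd `residual_sd_log2`, default 0.3)
  act on the log2 scale. A per-spot exponential draw instead would impose
  CV = 1 (≈1.85 log2 of noise), under which no fold change is recoverable.
* Planted signature genes take baselines above the background detection
  floor (a memoryless exponential shift by 4·`background_sd`): a fold
  change on a probe whose signal is buried in background noise is not
  identifiable by any method, and real signature genes are detectably
  expressed.
* The array bias is a random low-order polynomial in standardized log
  intensity with amplitude `array_bias_amplitude` (default 0.2 log2,
  amplitude 0 disables), the argument clamped to ±2 so the distortion
  stays bounded at the intensity extremes — a scanner-like bias that
  lowess can plausibly remove.
* Planted (non-null) probes are always annotated — one plants named genes
  — and the null-probe annotation rate is adjusted so the overall
  annotated fraction still meets its target.

`generate_companion_dataset()` builds the foreign-platform, gene-level
dataset for integration tests: its symbol universe overlaps the truth at
exactly the requested count (planted symbols first, so cross-platform
structure survives the cut), one foreign group (mES-analog) reuses the
stem reference profile, the others a somatic profile, plus an additive
batch offset (default +2 log2) and independent noise.
`generate_ct_table()` emits Ct values as `ct0 − true log2 expression +
noise`, with a null-class gene as the internal control.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: spatial artifacts and print-tip effects, dye
chemistry, probe-specific affinity and cross-hybridization, correlated
(gene-network) noise, outlier samples, and annotation errors. Recovery
rates on this generator are upper bounds on what the same thresholds
achieve on real arrays.

# Operating sizes used by the test suite

Chosen as representative desk-scale versions of the study conditions: unit
tests run on 150–5,000-probe experiments; the false-discovery calibration
uses 200 replicate two-group experiments of 2,000 probes; signature
recovery runs four 10,000-probe five-group experiments; the cross-platform
clustering property uses 50 seeds of an 800-probe experiment with a
300-symbol overlap. The full-scale defaults (44,000 probes) run in a few
minutes per experiment and produce the same qualitative behaviour.

# Known limitations

* Single-factor designs only: no covariates, paired structures, or
  gene-set testing.
* The shared-stem selection inherits the ±8-score convention; for designs
  with other group counts the threshold should be rescaled by the number
  of contributing contrasts.
* Cross-species integration relies on case-folded symbol identity, not
  orthology.
* Average-quantile normalization attenuates extreme fold changes under
  asymmetric differential expression (see above); effect-size estimates
  near the top of the intensity range are conservative.
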