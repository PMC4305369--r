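# stemsig

Signature analysis for single-channel microarray studies that compare
several cell types — built around the design of chicken stem-cell
transcriptomics: five cell populations (embryonic stem cells **cES**,
blastodermal cells **cBC**, primordial germ cells **PGC**, and two somatic
references **CEF** and **BM2**), three arrays each, ~44k probes of which
only ~58% carry a gene symbol.

The package covers the full chain:

* **Input** — GenePix-style `.gpr` scans (`read_gpr`), GAL-style
  annotation (`read_annotation`), design tables, TSV expression matrices.
* **Preprocessing** — normexp background correction
  (observed = Exp(α) signal + N(μ, σ²) background, corrected by
  E[signal | observed]), log2, within-array lowess against a
  pseudo-reference, between-array average-quantile normalization,
  duplicate-spot averaging (`preprocess_experiment`).
* **Differential expression** — per-probe group means with pooled
  variance, empirical-Bayes moderated t
  (s̃² = (d₀s₀² + d_g s_g²)/(d₀ + d_g), trigamma-matched prior),
  Benjamini–Hochberg correction, and dual-threshold calls:
  **U**p / **D**own when adjusted p < 0.05 **and** |log2FC| > 2, else
  **n** (`fit_group_model`, `estimate_prior`, `moderated_t`,
  `all_contrasts`).
* **FC-score signatures** — for each reference cell type, the score of a
  gene is the sum of its called log2 fold changes over the other groups
  (up to four terms, so ±8 corresponds to |log2FC| ≥ 2 against every other
  type). Cell-type-specific lists (`select_specific`), the shared
  stem/pluripotency set (score ≤ −8 in both somatic profiles,
  `select_shared_stem`), the germ signature (score ≥ +8 in the PGC-like
  profile, `select_germ`), and Venn partitions (`venn_partition`).
* **Integration** — probe→gene collapsing, cross-platform "virtual array"
  (common symbols → common-reference quantile normalization → per-dataset
  per-gene median centering), one-way-ANOVA gene ranking, PCA with
  replicate barycenters, hierarchical clustering with newick export.
* **qPCR** — comparative ΔΔCt relative quantification (RQ = 2^(−ΔΔCt),
  calibrator group at RQ = 1 by construction) and microarray concordance.
* **Synthetic data** — `generate_experiment` plants known
  group-specific, shared-stem and germ signatures in realistic raw scans
  (exponential signal, normal background, array-specific
  intensity-dependent bias, duplicate spots, partial annotation), plus a
  foreign-platform companion dataset and Ct tables, so every stage can be
  validated against ground truth.

## Worked example

```r
library(stemsig)

cfg <- simulation_config(n_probes = 5000, seed = 42)  # 5 groups x 3 arrays
ex  <- generate_experiment(cfg)

pp  <- preprocess_experiment(ex$scans, ex$design)
pp$normexp_params$cES_1
#> NormexpParams: mu = 108.1, sigma = 17.83, alpha = 965.2

fit   <- fit_group_model(pp$matrix)
prior <- estimate_prior(fit)
prior
#> ModerationPrior: d0 = 11.027, s0_sq = 0.08995

tabs <- all_contrasts(fit, prior, alpha = 0.05, lfc = 2)
pairwise_de_matrix(tabs, cfg$groups)
#>     CEF BM2 cES PGC cBC
#> CEF   0  80 168 188 168
#> BM2  80   0 157 172 152
#> cES 168 157   0 100  80
#> PGC 188 172 100   0 100
#> cBC 168 152  80 100   0

profiles <- lapply(cfg$groups, build_profile, tables = tabs,
                   groups = cfg$groups, annotation = ex$annotation)
names(profiles) <- cfg$groups
report <- signature_report(profiles, somatic_refs = c("CEF", "BM2"),
                           germ_ref = "PGC", score_threshold = 8)
report
#> SignatureReport
#>   specific CEF   :   40 probes (40 genes)
#>   specific BM2   :   40 probes (40 genes)
#>   specific cES   :   39 probes (39 genes)
#>   specific PGC   :   59 probes (59 genes)
#>   specific cBC   :   40 probes (40 genes)
#>   shared stem   :   34 genes (score <= -8 in each of CEF, BM2)
#>   germ          :   60 genes (score >= 8 in PGC)

head(report$germ, 3)
#>   gene_symbol  probe_id fc_score
#> 1   GENE02151 TID002151 12.43151
#> 2   GENE03820 TID003820 12.42457
#> 3   GENE03731 TID003731 12.29060
```

Reading the output: the generator planted 40 specific genes per cell type
(the 59 PGC-specific hits are the 60 planted germ genes — the germ
signature *is* the PGC-specific profile), 88 shared-stem and 60 germ
genes at a 3-log2 effect with 0.3-log2 residual noise. Specific and germ
classes are recovered essentially completely with no false positives. The
strict shared-stem rule (score ≤ −8 in *both* somatic profiles, i.e. three
called contrasts summing past −8) sits one noise standard deviation from
its expected value at this noise level, so only part of the planted
shared set clears it — at residual sd 0.2 the same rule recovers ≥ 97%;
the methods vignette (`vignettes/stemsig-methods.Rmd`) quantifies this
margin.

Cross-platform clustering and qPCR follow the same pattern; see
`?build_virtual_array`, `?hierarchical_tree`, `?relative_quantification`.

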