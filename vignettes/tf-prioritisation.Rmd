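---
title: "Prioritising master-regulator transcription factors from co-expression networks"
author: "tfprio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritising master-regulator transcription factors from co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Directed differentiation of pluripotent stem cells towards a specialised
cell type — for example liver sinusoidal endothelial cells (LSECs), the
scavenger endothelium of the liver — is often limited by ignorance of the
transcription factors (TFs) that drive the fate decision. Ranking TFs by
differential expression alone is a poor guide: broadly acting stress TFs
dominate fold-change rankings, and a TF's fold change says nothing about how
many downstream targets it controls in the transcriptional programme of
interest.

`tfprio` implements an integrative prioritisation: a TF is a strong
candidate master regulator when it (i) sits centrally in a co-expression
module, (ii) has its DNA-binding motif enriched in the regulatory regions of
that module's genes, (iii) belongs to a module that is specifically active
in the target cell type, and (iv) is itself up-regulated in the target
population relative to the cells one would engineer. Candidates passing all
four filters are ranked by the fraction of their module they regulate.

## Pipeline stages and their models

### Ingestion and merging (`filter_samples`, `aggregate_probes`, `select_platforms`, `assemble_matrix`)

Microarray meta-analyses mix platforms that measure different gene sets.
Sample inclusion is rule-based: an organism whitelist, a label whitelist
(e.g. biotin), a platform-prefix whitelist, and a case-insensitive substring
denylist over free-text sample characteristics (default `carcinoma`,
`tumor`, `tumour`, `cancer`, `HCC`) standing in for "non-cancerous origin",
which no repository encodes directly. Probe intensities are aggregated per
gene by geometric mean. Platform selection maximises
(total samples) × (genes shared by all chosen platforms), searched
exhaustively over subsets (platform counts are small; a greedy forward
search covers the hypothetical >20-platform case). A `forced` argument
allows retaining a platform that is the only source of a key cell type even
when it shrinks the common gene set. Linear-scale values are transformed as
`log2(x + 1)`, which tolerates zeros and is stable at low intensities.
`quantile_normalize()` (via `limma`) is a documented, weaker stand-in for
probe-level normalisation of raw arrays, for users starting from
already-summarised matrices.

### Batch adjustment (`fit_combat`, `adjust_combat`)

Platform and study effects are removed with the parametric empirical-Bayes
location-scale model: gene-wise standardisation around a batch-size-weighted
grand mean, per-batch location/scale effects, normal and inverse-gamma
priors moment-matched across genes, and iterated conditional posterior means
(tolerance `1e-4`, at most 500 iterations — values chosen for determinism;
the method itself does not prescribe them). Constant genes are flagged and
passed through. Two properties of this estimator are worth stating because
they are easy to mis-expect: the EB shrinkage leaves a *per-gene* residual
batch-mean difference of the order of half the sampling noise of a batch
mean (the systematic shift is removed; individual genes retain
`O(sd/sqrt(n))` residuals), and per-gene overall means are preserved only up
to the same shrinkage residual, not exactly. The implementation agrees with
the reference `sva::ComBat` to ~1e-6 on identical inputs, which is the
operative correctness check.

### Gene filtering (`filter_genes`)

TFs are kept when they vary at least twofold across samples, read as
`max/min >= 2` on the linear scale, i.e. a log2 range of at least 1 (the
alternative all-pairs reading is not what a variability filter means).
"Variability" for non-TFs is the standard deviation of the per-sample log2
values — identical to the SD of log2 fold changes against the gene mean.
Non-TFs either fill a total gene cap after the TFs or pass an explicit SD
threshold.

### Signed network and modules (`pick_soft_threshold`, `tom_matrix`, `detect_modules`)

Gene-gene Pearson correlations are mapped to a signed similarity
`(1 + cor)/2` and raised to a soft-thresholding power. The power is chosen
by approximate scale-free topology: connectivities are binned into 10
equal-occupancy bins and the log10 bin *density* (count per unit
connectivity) is regressed on log10 mean bin connectivity; equal-occupancy
bins make raw frequencies constant by construction, so density is the
quantity whose power-law decay the fit can detect. The fit is the R² signed
to favour negative slopes. Two guards qualify a power: the fit must reach
`r2_cut` (default 0.8) and the slope must lie in `slope_range` (default
-3 to -1). The slope band is the standard sanity check on the implied
scale-free exponent: on module-structured data low powers can produce a
high R² with a far steeper slope than any scale-free degree distribution
admits, which describes a compact, non-scale-free connectivity
distribution; accepting such a power collapses the network into one blob.
If no power satisfies both conditions the slope condition is dropped, and
failing that the argmax-fit power is used.

Modules are branches of an average-linkage tree of `1 - TOM` (topological
overlap) cut statically at `cut_height = 0.99`; branches smaller than 30
genes go to grey. A static cut is deterministic and transparent, but
average linkage chains weakly correlated genes onto strong branches just
below any fixed cut, so each raw branch is pruned by module membership:
genes whose correlation with the branch eigengene (kME) is below
`kme_prune = 0.5` return to grey. The floor deliberately re-uses the same
kME = 0.5 threshold the downstream TF filter applies — a gene that would
not count as "central" downstream should not define the module either. The
test suite's planted-module benchmarks (adjusted Rand index of recovered
versus planted assignments) exercise exactly this failure mode; pruning can
be disabled with `kme_prune = 0`.

Eigengenes are first right-singular vectors of the per-gene standardised
module submatrix, unit norm, oriented to correlate non-negatively with the
module mean profile. Modules whose eigengene dissimilarity `1 - cor` falls
below `merge_cut = 0.3` are merged iteratively, closest pair first. Final
labels follow the conventional size-ordered colour palette (turquoise,
blue, brown, ...), which makes labels reproducible across runs.

### Motif enrichment and regulons (`recovery_auc`, `module_enrichment`, `build_regulons`)

A motif ranking database stores, per motif, a complete ranking of all genes
(rank 1 = best). For a module gene set `S`, the recovery curve
`rec(x) = |{g in S : rank(g) <= x}|` is integrated over the top
`top_frac = 0.05` of the ranking and normalised to `[0, 1]`. AUCs are
standardised over all motifs in the database to a normalised enrichment
score, `NES = (AUC - mean)/sd`; motifs with `NES >= 3` are kept. The
leading edge of a kept motif contains the set members ranked at or before
the position maximising `rec(x) - (mean(x) + 2 sd(x))`, the critical curve
taken over all motifs — the package's reimplementation of
significant-target extraction. Regulons union the leading edges of a TF's
enriched motifs per module, keeping the best NES. Only direct motif-to-TF
annotations are used; orthology-inferred tiers would enlarge regulons at
the price of annotation confidence.

### Module activity (`gsva_scores`, `celltype_activity`, `go_fisher`)

Per-sample module activity uses gene-set variation scoring with its
reference defaults (Gaussian kernel CDF with bandwidth `sd/4`, rank weight
exponent `tau = 1`, `mx_diff` scoring): per sample, genes are ranked by
their kernel-CDF statistic, and a weighted Kolmogorov–Smirnov random walk
(weights `|N/2 - rank|^tau` inside the set, uniform decrements outside)
yields a score in `[-1, 1]`. A module is "active" in the target cell type
when its mean score over target samples strictly exceeds the pooled mean
over all other samples; a stricter per-cell-type mode
(`per_type = TRUE`) requires beating every other cell type individually.
Module annotation uses the one-sided Fisher exact test (upper
hypergeometric tail) per GO term, keeping the 15 smallest-p terms per
category; annotations are expected pre-propagated to ancestors, with a
minimal `is_a`/`part_of` OBO propagation helper provided so that ontology
releases need not be bundled.

### Differential expression (`nb_wald_de`, `tpm`, `wilcoxon_markers`, `consensus_markers`)

The bulk contrast (target cells versus the engineered reference population)
is fitted with a deliberately transparent negative-binomial Wald test:
median-of-ratios size factors, method-of-moments gene-wise dispersions on
normalised counts (floored at 1e-8, no trend shrinkage), an IRLS fit of the
two-group log-linear model with log size factors as offsets, a normal Wald
p-value and BH adjustment. A gene is *significant* only when `padj < 0.05`
and `|log2FC| >= 1` — fold changes under two are treated as biologically
meaningless. This simplified estimator trades the reference tool's
shrinkage machinery for auditability; on null NB simulations its raw-p
rejection rate at 0.05 is ~0.066 (slightly liberal, as plug-in dispersion
Wald tests are at 10 samples per group), and its fold-change estimates
correlate >0.95 with the reference implementation on planted data. It is
exercised only on synthetic counts. TPM quantification divides counts by
merged (union) exon lengths and rescales columns to 1e6. Marker testing in
cell-resolved data uses the two-sided Wilcoxon rank-sum test (exact by
enumeration when both sides have at most 8 observations and no ties;
tie-corrected normal approximation otherwise) with BH correction, and
cross-dataset marker consensus keeps genes exceeding a sevenfold change in
every validation dataset, ranked by the meta-analysis fold change
(infinite fold changes from zero denominators survive the threshold).

### Integration (`rank_tfs`, `export_network`)

Candidates are (TF, module) pairs with a regulon. All four predicates —
DE-up and significant; kME strictly above 0.5 in that module, whether or
not the TF is assigned to it (a TF may therefore appear in several rows,
matching the observation that one TF can be central to two modules);
module active in the target cell type; best NES at least 3 — must hold.
Survivors are ranked by `|regulon ∩ module| / |module|` descending, ties by
absolute log2 fold change then symbol. Network export writes node/edge
tables for standard visualisation tools: per TF at most the 20 most
differentially expressed targets, node colour = module colour with
central TFs recoloured into the module of interest, ellipse/rectangle
shapes for up/down regulation, and node size `10 + 2 × outdegree` (the
underlying convention only requires size to grow with target count; the
affine map is a rendering choice).

## The synthetic-data generator

`simulate_expression()` plants the structure the network stage assumes:
blocks of genes loading (`U(0.5, 1)`; uniform loadings keep every module
gene informative) on latent factors whose means differ by cell type
(default +2 in the module's "own" cell type, -1 elsewhere, unit factor
variance), an additive per-batch array shift applied to all genes
(round-robin batch assignment, so batch is not confounded with cell type),
and Gaussian noise (`sd = 0.5`). Defaults — 2000 genes, three modules of
50, three cell types × 20 samples, two batches shifted by 0/1 — are the
scale at which the planted-recovery benchmarks run. `simulate_ranking_db()`
plants one motif per TF whose targets occupy the top percentile block of
the ranking among fully random decoys; `simulate_counts()` draws NB counts
with the planted log2 fold change split symmetrically across groups;
`simulate_study()` wires all of it into a complete end-to-end fixture with
one planted master regulator per module. `positivity_summary()` is the
small reporting helper for count-based positivity readouts, with a Wilson
score interval (preferred over the Wald interval near 0% and 100%).

What the generator does *not* emulate: probe-level microarray artefacts,
heavy-tailed and correlated noise, library-composition shifts, overlapping
modules, or indirect regulation. Passing the planted-truth benchmarks
therefore demonstrates internal consistency of the machinery, not
performance on real arrays; the thresholds (kME 0.5, NES 3, twofold DE) are
the workflow's standard operating points, not values validated on this
synthetic distribution.

## Numerical choices and degenerate inputs

* Quantile-normalisation ties receive the mean of the tied reference block.
* Constant genes: an error in the correlation stage (undefined), a flagged
  pass-through in batch adjustment, a floored bandwidth (1e-8) in activity
  scoring.
* NES requires at least 2 motifs and a non-degenerate AUC spread; module
  enrichment requires at least 5 module genes in the database.
* The scale-free fit declares itself degenerate when connectivities are
  essentially constant (relative spread below 1e-4) or fewer than 3 usable
  bins remain.
* Size factors are defined only up to a common constant; rescaling one
  library rescales its factor relative to the others and leaves normalised
  counts unchanged up to that constant.
* All-zero genes receive NA statistics in the DE table and are excluded
  from BH; all-zero TPM columns stay zero with a warning.
* Platform-selection ties break to the lexicographically smallest id set;
  module-size ties break by first gene index; ranking ties break by
  |log2FC| then symbol.

## Problem sizes

The test-suite benchmarks run at 2000 genes × 60 samples for module
recovery, 201 motifs × 2000 genes for motif recovery and false-positive
calibration, 2000 genes × 20 samples × 50 replicates for DE calibration,
and a 1000-gene end-to-end study — sizes at which every property the suite
asserts is stable across seeds while the whole suite stays fast enough to
run routinely.

## Known limitations

* Pearson correlation misses non-linear and combinatorial regulation; genes
  under combinatorial control may land in grey or in an unrelated module
  even when their regulator is correctly prioritised.
* The DE stage has no dispersion or fold-change shrinkage and is slightly
  liberal at small sample sizes; it is not a replacement for the reference
  tools on real data.
* The static tree cut with kME pruning is deterministic but cruder than
  dynamic tree cutting on real dendrograms with nested module structure.
* Exhaustive platform search is exponential in the number of platforms and
  switches to a greedy search above 20.
* No production motif database ships with the package; rankings must be
  supplied (TSV or feather) or simulated.
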