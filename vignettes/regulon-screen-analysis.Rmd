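---
title: "Regulon-based analysis of single-cell CRISPR screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulon-based analysis of single-cell CRISPR screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regulonscreen)
library(dplyr)
```

## The problem

Pooled CRISPR screens with a single-cell transcriptomic readout (CROP-seq
and relatives) link each cell's perturbation — identified by the sgRNA it
carries — to its expression profile. Two features of these data make naive
per-gene analysis fragile. First, single-cell counts are sparse and noisy,
so the expression change of any one gene after a perturbation is poorly
estimated unless hundreds of cells carry the guide. Second, CRISPR editing
is imperfect: a cell can carry a guide whose target protein remains
functional (unedited, or carrying an in-frame repair), so a guide's cell
population is a mixture of truly perturbed and "escaped" cells.

`regulonscreen` addresses both. It reads perturbation effects on *regulon
activities* — rank-based scores over transcription-factor target-gene sets,
which aggregate tens of genes and are far more stable at low cell numbers
than single genes — and it removes escaped cells with a perturbation
probability model followed by a two-component Gaussian mixture. Around this
core it provides the screen's standard bookkeeping (QC, unique-guide
selection, guide-library accounting), module-level map inference, a
marker-panel regulator score, and a benchmarking layer that quantifies the
regulon-versus-gene robustness claim on data with known ground truth.

## The pipeline, stage by stage

### Input model and quality control

Counts enter as a CellRanger-style sparse triplet (MTX + features +
barcodes); guide assignments and the guide library are TSVs; regulons are a
GMT file, one TF per line. Regulon *inference* is out of scope: regulons
are consumed as given (in practice from a SCENIC-style workflow).

Cell QC keeps cells with more than 200 and fewer than 6,000 detected genes
and less than 10% mitochondrial UMIs — all strict inequalities, matching
the usual phrasing of these filters. Mitochondrial genes are recognized by
a configurable symbol prefix (default `mt-`, case-insensitive), since no
universal rule exists. Cells are then restricted to those with exactly one
distinct assigned guide; multiplicity of the *same* guide (several UMIs)
does not disqualify a cell. Genes used for activity scoring must have at
least 6 total UMIs and be detected in at least 1% of cells.

### Regulon activity

For each cell, all genes are ranked by decreasing raw count and the
activity of a regulon is the area under its recovery curve within the top
`top_frac` of the ranking, normalized by the maximal achievable area, so
values lie in [0, 1]. Ranking raw counts makes the score invariant to
per-cell scaling, so it can be computed before or after normalization.
Two choices are deliberately exposed because the upstream convention does
not pin them down: `top_frac` defaults to 0.05 (the common default of
rank-recovery scoring), and ties are broken by average rank — a
deterministic rule — with a seeded random mode available for
cross-checking. Average-rank ties make the score reproducible bit-for-bit,
at the cost of slightly conservative scores for genes tied at the top-set
boundary.

### Effect sizes and regulation pairs

The effect of perturbing target \(t\) on regulon \(r\) is

\[ e_{tr} = \bar A_{tr} - \bar A_{0r}, \]

the mean activity in \(t\)'s cells minus the mean in reference cells, with
a two-sided Wilcoxon rank-sum p-value per pair. sgRNAs supported by fewer
than 40 cells are removed first; a target survives if any of its guides
survives. The reference defaults to non-targeting (NT) control cells; an
"all other cells" mode exists because "non-target cells" is genuinely
ambiguous in common usage. Pairs with \(p < 0.05\) (strict) are retained as
regulations and split by sign into activating and repressive classes.

### Modules and the module map

Spearman correlations between effect profiles — across targets and across
regulons — feed k-means (best of 50 seeded restarts; defaults k = 4 for
perturbation modules, k = 5 for regulon modules). For each perturbation
module \(P_i\), regulon module \(R_j\) and sign class, with \(N\) the
class's regulations, \(K_P\) from \(P_i\), \(K_R\) into \(R_j\) and \(k\)
in both, significance comes from the hypergeometric law

\[ P(X = k) = \frac{\binom{K_P}{k}\binom{N-K_P}{K_R-k}}{\binom{N}{K_R}}. \]

The default test statistic is the upper tail \(P(X \ge k)\): the point
probability alone is not a significance measure, though a `pmf` mode is
kept for bit-compatibility with workflows that use it directly.
Benjamini–Hochberg adjustment pools all \(P_i \times R_j \times\) sign
tests jointly by default (per-class pooling is available; the choice is
recorded in the output); edges with adjusted \(p < 0.05\) are kept with
weight \(-\log_{10}\) adjusted \(p\). Constant effect vectors get Spearman
correlation 0, with a warning, rather than NaN.

### Filtering unperturbed cells

Standardized expression of the most variable genes (default top 2,000) is
regressed on guide indicators with a multi-response elastic net
(`l1_ratio` = 0.5, penalty chosen by 5-fold cross-validation). For a cell
carrying guide \(g\), let \(r_1\) be its residual sum of squares under the
fitted model and \(r_0\) the RSS with \(g\)'s coefficient row zeroed. The
perturbation probability is the equal-prior Gaussian posterior

\[ p = \frac{e^{-r_1/2\sigma^2}}{e^{-r_1/2\sigma^2} + e^{-r_0/2\sigma^2}}, \]

with \(\sigma^2\) the pooled residual variance. This is this package's
concrete definition of the probability (the general strategy of regressing
expression on guide indicators admits many posteriors); it was chosen as
the simplest model-consistent one, and it reproduces the two qualitative
behaviours that matter: NT cells centre at 0.5, and targeted guides with
real effects become bimodal. One implementation detail is load-bearing:
each cell's contrast is evaluated with coefficients fitted on the *other*
cross-validation folds. Without this cross-fitting, coefficients partially
fit to the cell itself inflate every probability above 0.5 and wash out
the NT calibration.

Per sgRNA (per target gene optionally — descriptions of this step
alternate between the two groupings, so both are exposed), a two-component
Gaussian mixture is fitted to the probabilities by EM: 10 restarts with
k-means++-style initial means, best log-likelihood kept, components
ordered by mean, standard deviations floored at a small multiple of the
data's spread to avoid degenerate spikes. A cell whose posterior for the
higher-mean ("perturbed") component is strictly below 0.05 is labelled
unperturbed and removed from expression-level analyses. Groups that are
too small (< 10 cells), constant, or non-convergent are flagged and passed
through unfiltered — filtering should fail open, not silently delete
cells.

### Regulator score

For perturbation \(i\) and a marker panel of \(k\) genes (default: the
nine hepatocyte markers Alb, Ttr, Mup20, Sult1a1, Cyp3a13, Abcc3, Tff3,
Trf, Fga),

\[ \mathrm{Score}_i = \frac{1}{k}\sum_{j=1}^{k} \log_2 \mathrm{FC}_{ij}, \]

where \(\mathrm{FC}_{ij}\) is the ratio of mean normalized marker
expression in \(i\)'s (filtered) cells to the reference mean. Means are
taken on the linear counts-per-10k scale — the plain reading of
"normalized expression" — and a pseudocount (default 0.01) is added to
both means to stabilize zero-expression markers; no zero-handling rule is
standard, so the value is exposed. A positive score means the knockout
*raises* marker expression: the gene is a candidate negative regulator of
the marker-defined fate.

### Benchmarking readouts

Three instruments quantify how trustworthy an effect readout is:

* **Consistency**: each target's relative effect is its Spearman
  correlation with a reference target over the method's 200 most variable
  features; two methods are compared by correlating their per-target
  profiles.
* **Co-directionality / robustness score**: the estimator is run on the
  full data and on 100 per-group downsamples; \(D_{ij}\) is the fraction
  of downsamples whose coefficient sign for feature \(i\), target \(j\)
  matches the full-data sign, and \(RS_j = \lVert D_{\cdot j} - \mathbf 1
  \rVert_2\) (0 = perfectly stable, \(\sqrt{n}\) = total disagreement).
  Signs, not magnitudes, are compared because most coefficients sit near
  zero. Features are z-scored per feature before estimation, the natural
  normalization when none is prescribed. The estimator is pluggable so
  external effect matrices can be benchmarked; a mean-difference estimator
  ships with the package. A configurable inclusion rule (default: groups
  with more than 600 perturbed cells) mirrors the usual eligibility filter
  for this analysis.
* **Cell-number sweep**: for a grid of subsample sizes, the median (over
  seeded subsamples) Spearman correlation between subsample feature means
  and full-group feature means, and the smallest size whose median reaches
  a threshold (default 0.9).

## What the simulator emulates — and what it does not

Every downstream stage is validated against `simulate_screen()`, which
generates a screen with complete ground truth. Its defaults are fixed once
to a pilot-screen-like design: 6 targets x 3 guides + 4 NT controls, 100
cells per guide, a 300-gene universe containing 10 disjoint regulons of
8–12 genes (the first regulon carries the 9-marker panel), negative
binomial baseline counts (mean 2, size 2 — overdispersion typical of
shallow UMI data), multiplicative log2-scale effects on regulon member
genes, logistic dropout with midpoint −3 on the log-mean scale (mild, so a
2-fold true effect stays close to 2-fold in the observed means), an
editing-escape rate of 0.2, and strict one-guide-per-cell assignment with
an optional Poisson(0.3) multiplicity mode reflecting low-MOI infection.
Escaped cells draw from the unperturbed distribution *exactly* — the
two-component assumption of the mixture filter holds by construction.

The simulator deliberately omits ambient RNA, doublets, batch structure,
cell-cycle covariation and correlated regulons. Green tests therefore show
that the algorithms are implemented correctly and behave as designed under
the stated generative model; they do not show that the model captures
every failure mode of real organoid screens — in particular, partial
knockdown (rather than all-or-nothing escape) would blur the mixture that
the GMM separates.

Simulated problem sizes throughout the tests and the acceptance script
(hundreds of cells per guide, 200–300 genes, 10 regulons) are the
package's chosen working scale for validation: large enough for the
statistical properties to be measurable, small enough to iterate on.

## Numerical and design choices

* Log-normalization uses natural log, counts-per-10k; both are
  configurable and recorded in the pipeline config dump.
* The hypergeometric probabilities are computed in log space with
  `lchoose`, exact well beyond the N involved here; tests check them
  against exhaustive subset enumeration.
* k-means with k equal to the number of labels returns singleton modules
  directly (inertia 0) instead of invoking the stochastic search.
* Wilcoxon tests use the normal approximation with continuity correction
  (activity values tie heavily; the exact test would refuse ties anyway).
* All randomness — simulator, cross-validation folds, EM restarts, k-means
  restarts, downsampling — flows through per-call seeds, and the pipeline
  writes MD5 checksums of every artifact; two runs with the same config
  and seed are byte-identical.
* A screen whose QC removes every cell warns and returns an empty matrix
  rather than erroring, so callers can distinguish "bad thresholds" from
  "malformed input".

## Known limitations

* The perturbation probability assumes one guide per cell (enforced
  upstream) and equal priors between "carries the signature" and "does
  not"; heavily unbalanced escape rates would shift the NT calibration.
* Regulon activity floors at 0: strong *repressive* effects on a weakly
  expressed regulon compress into a small dynamic range, so repressive
  effect sizes are systematically smaller in magnitude than activating
  ones at equal true fold change (their p-values remain well calibrated).
* The co-directionality matrix is only informative for features whose
  full-data sign is itself stable; with truly null features, sign
  agreement hovers near 0.5 by construction and inflates RS.

## A worked example

```{r example, eval = FALSE}
sim <- simulate_screen(sim_config(seed = 1))
m <- sim$screen |>
  qc_filter_cells(min_genes = 10) |>
  select_unique_sgrna_cells(sim$assignments, sim$library) |>
  filter_genes_for_activity() |>
  normalize_log()

act <- score_aucell(m, sim$truth$regulons)
eff <- compute_effect_matrix(act, target_groups(m) |> filter_min_cells(40))
pairs <- test_regulations(eff)
pm <- kmeans_modules(correlate_spearman(eff, "targets"), k = 4, seed = 1)
rm_ <- kmeans_modules(correlate_spearman(eff, "features"), k = 5, seed = 1)
edges <- build_module_map(pairs, pm, rm_)
autoplot(eff)
```

The same flow, file-in/file-out with a config dump and checksums, is
`run_pipeline()`; a command-line wrapper lives in
`inst/scripts/screen-pipeline.R`.
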