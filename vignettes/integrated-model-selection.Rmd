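---
title: "Integrated multi-criteria selection of segmentation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrated multi-criteria selection of segmentation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segsel)
```

## The problem

Choosing "the best" semantic-segmentation model for a clinical task is a
multiple-criteria decision: segmentation accuracy (IoU, pixel accuracy,
recall, precision, F1), model complexity (parameter count, multiply-accumulate
operations) and inference speed (FPS) pull in different directions, and no
single metric orders the candidates. `segsel` implements an integrated
evaluation pipeline for this situation, built from four stages:

1. **Pixel metrics.** Predicted and ground-truth masks are compared pixel by
   pixel as a binary classification (foreground vs background), yielding
   TP/FP/TN/FN and from them IoU = TP/(TP+FP+FN), ACC, RE, PR and F1. A
   probability map is binarized at a threshold (default 0.5, with ties at the
   threshold counted positive). These metrics, measured over a test set, form
   the accuracy columns of a decision matrix.
2. **Decision matrix and normalization.** The $n \times p$ matrix $X$ holds
   the raw value $x_{ij}$ of criterion $j$ for model $i$, in mixed units.
   Each column is min–max normalized, with cost criteria (Params, MACs)
   inverted so that 1 is always best:
   $x'_{ij} = (x_{ij}-x_{\min})/(x_{\max}-x_{\min})$ for benefit,
   $x'_{ij} = (x_{\max}-x_{ij})/(x_{\max}-x_{\min})$ for cost.
3. **Objective weights (CRITIC).** Criterion $j$'s weight combines its
   contrast intensity $\sigma_j$ (standard deviation of the normalized
   column) with its conflict $R_j=\sum_{k}(1-r_{jk})$ against the other
   criteria; the information amount is $C_j=\sigma_j R_j$ and
   $\omega_j = C_j/\sum_j C_j$. The CRITIC score of a model is
   $S_i = \sum_j \omega_j x'_{ij}$. In parallel, an expert-elicited weight
   vector gives a subjective score $S_{i,sub} = \sum_j w_j x'_{ij}$.
4. **Final score and rank.** $S_{final} = \delta S_i + \mu S_{i,sub}$ with
   $\delta + \mu = 1$, default $\delta=\mu=0.5$; models are ranked by
   descending final score at full precision.

The package ships a 21-alternative × 8-criterion benchmark matrix (seven
gastric-polyp segmentation architectures, each with three encoders) together
with its published score columns, as the reference worked example.

```{r}
ev <- evaluate_matrix(table6_fixture())
head(ev$scores[order(ev$scores$rank), ], 3)
```

## Calibration of the CRITIC convention

The source of the benchmark states that $r_{jk}$ is the *Spearman* rank
correlation, but leaves open whether correlations are taken on the raw or the
normalized columns and whether the SD uses the sample or population divisor.
All four toggles are exposed; calibration against the published score table
decides the default:

* **Correlation kind.** Pearson correlation on the normalized matrix
  reproduces every one of the 21 published CRITIC scores to within ±0.005 —
  exact at the printed 2-decimal precision. Spearman deviates by up to 0.061
  (e.g. 0.87 instead of the published 0.84 for the top-ranked model), and no
  other toggle rescues it. Pearson is also what the original CRITIC
  formulation uses. The package default is therefore
  `corr_kind = "pearson"`; `"spearman"` remains available, and
  `reproduce_table6(corr_kind = "spearman")` emits its per-row deviation
  table.

```{r}
rep <- reproduce_table6()
max(rep$critic_dev)
max(reproduce_table6(corr_kind = "spearman")$critic_dev)
```

* **SD form.** Sample vs population SD differ by the constant factor
  $\sqrt{n/(n-1)}$ per column, which cancels in the weight normalization;
  the two settings give identical scores. The default is documented as
  `"sample"`.
* **Correlation basis.** Correlations default to the normalized matrix, so
  cost criteria are direction-consistent before conflict is measured — the
  premise of CRITIC's "conflict" notion. `corr_basis = "raw"` exists for
  sensitivity analysis only.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `threshold` | 0.5 | probability-map binarization cut, in (0,1); ties positive |
| `pooling` | `"micro"` | test-set aggregation: pooled counts (robust to image-size variation) vs per-image mean |
| `delta` | 0.5 | weight of the objective score in the final combination, in [0,1] |
| subjective weights | IoU 0.3, ACC/RE/PR/F1 0.05, Params/GMACs 0.1, FPS 0.3 | expert scheme; accuracy and speed dominate because a fast, accurate delineation is the clinical requirement |
| `constant` | `"error"` | a zero-contrast criterion distorts weights silently; mapping to zeros requires an explicit opt-in |

Weights are configuration, not code: criteria and weight files (flat YAML or
CSV) can replace the packaged scheme. Weight vectors must sum to 1 within
1e-9; renormalization happens only behind an explicit flag, with a warning.

## Numerical conventions

* **Degenerate counts.** When both masks contain no positives
  (tp=fp=fn=0), the overlap metrics are defined as 1, so a prediction
  identical to its ground truth always scores perfectly; a zero denominator
  with disagreement present scores 0. All-zero counts are an error.
* **Display rounding.** Scores are ranked at full double precision and only
  *displayed* rounded half-up to two decimals (`round_half_up`), matching
  how the reference table is printed; base `round()`'s half-to-even rule
  would disagree with the printed values on exact ties.
* **Tie-breaks.** Ranks break ties by higher CRITIC score, then higher
  subjective score, then lexicographic identifier. This chain is a package
  convention — the reference table never ties — but it makes ranking
  deterministic.
* **Spearman ties** use average ranks, the standard convention.
* The conflict sum $R_j$ includes the self term $1-r_{jj}=0$, harmless and
  literal.

## What the synthetic generators do and do not establish

`gen_mask_pair()` builds mask pairs that hit requested TP/FP/FN counts
*exactly*: ground truth occupies a leading row-major block, false positives
toggle a seeded subset of the background. This gives the metric engine an
airtight round-trip oracle, but the masks are geometrically unrealistic — no
connected blobs, no boundary structure, no endoscopic texture. A green
metric-engine test therefore establishes arithmetic correctness of the
counting and formulas, not anything about real-image behavior.
`gen_random_matrix()` similarly produces decision matrices with controlled
structure (independent, rank-correlated via a Gaussian latent factor, or
with a planted dominant row) to exercise CRITIC's conflict logic; it does
not emulate the value distributions of real benchmarks. All generators take
explicit seeds and leave the global RNG state untouched.

## Design choices made here

* **Micro pooling by default** over a test set: pooled counts are robust to
  image-size variation (the benchmark's source images range from 356×302 to
  1296×1084 pixels); the per-image mean is available since the published
  aggregation is unstated, and the two differ in general.
* **Raster formats.** Masks are read from plain-text 0/1 grids and netpbm
  PBM/PGM (ASCII P1/P2 and binary P4/P5), any nonzero pixel counting as
  foreground. PNG is not supported: it would require a decoding dependency
  the package deliberately avoids.
* **Config dialect.** Criteria and weight configs use a small flat YAML
  subset (lists of `key: value` mappings, comments allowed) read by a
  built-in parser, or equivalently CSV; nothing nested is accepted.

## Limitations

* Strictly two-class masks; multi-class segmentation is out of scope.
* No resizing or interpolation of masks — shapes must already agree.
* Complexity and speed criteria (Params, MACs, FPS) are decision-matrix
  *inputs*; the package does not measure live networks.
* Min–max normalization is sensitive to the alternative set: adding or
  removing a model rescales every column, so scores are comparable only
  within one matrix.
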