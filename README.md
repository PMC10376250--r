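# segsel — integrated multi-criteria selection of segmentation models

Picking a semantic-segmentation model for deployment is rarely decided by a
single number: overlap accuracy (IoU, F1), pixel accuracy, recall and
precision trade off against model complexity (parameters,
multiply–accumulate operations) and inference speed (FPS). `segsel` treats
the choice as a multiple-criteria decision-making (MCDM) problem, aimed at
anyone benchmarking candidate models — the motivating use case is selecting
a CNN for automated gastric-polyp segmentation in endoscopic images.

The pipeline:

1. **Pixel metrics** from predicted vs ground-truth binary masks, via the
   confusion counts TP/FP/TN/FN:
   `IoU = TP/(TP+FP+FN)`, `ACC = (TP+TN)/n`, `RE = TP/(TP+FN)`,
   `PR = TP/(TP+FP)`, `F1 = 2·PR·RE/(PR+RE)`; probability maps are
   binarized at a 0.5 threshold.
2. **Min–max normalization** of the n×p decision matrix, benefit criteria
   as `(x−x_min)/(x_max−x_min)`, cost criteria inverted.
3. **CRITIC objective weights**: `ω_j ∝ σ_j · Σ_k (1−r_jk)` — contrast
   intensity times inter-criteria conflict — and objective scores
   `S_i = Σ_j ω_j x′_ij`.
4. **Subjective scores** from an expert weight vector (default: IoU 0.3,
   ACC/RE/PR/F1 0.05 each, Params/GMACs 0.1 each, FPS 0.3).
5. **Final score** `S_final = δ·S_i + μ·S_i,sub` with `δ = μ = 0.5`, and a
   deterministic rank.

A published 21-model × 8-criterion gastric-polyp benchmark ships as the
reference fixture, with its printed score columns for regression.

## Worked example

```r
library(segsel)
ev <- evaluate_matrix(table6_fixture())
head(ev$scores[order(ev$scores$rank), ], 3)
#>          alternative critic subjective final rank
#>  UNet++/MobileNet v2   0.84       0.88  0.86    1
#>  DeepLabv3+/ResNet50   0.81       0.86  0.83    2
#>     LinkNet/ResNet50   0.81       0.86  0.83    3
```

UNet++ with the MobileNet v2 encoder wins on the objective (CRITIC 0.84),
subjective (0.88) and combined (0.86) scores: it is not the most accurate
model in the benchmark, but its accuracy/efficiency trade-off dominates. The
computed columns reproduce all 21×3 published scores at their printed
2-decimal precision (see `reproduce_table6()` for the deviation table). The
CRITIC weights themselves show why speed discriminates:

```r
round(unclass(critic_weights(critic_diagnostics(normalize_matrix(table6_fixture())))), 4)
#>    IoU    ACC     RE     PR     F1 Params  GMACs    FPS
#> 0.0844 0.0863 0.1706 0.0848 0.0882 0.1345 0.1622 0.1890
```

The five accuracy metrics are highly correlated (low conflict, low weight);
FPS and complexity disagree with them and earn the largest objective
weights.

One calibration note: the benchmark's own description names the Spearman
rank correlation for the conflict term, but only Pearson correlation on the
normalized matrix reproduces its printed CRITIC column (±0.005 on all rows;
Spearman deviates by up to 0.061). The package defaults to the calibrated
Pearson convention and keeps `corr_kind = "spearman"` as a toggle; see the
vignette (`vignettes/integrated-model-selection.Rmd`).

## Command line

```sh
SEGSEL=$(Rscript -e 'cat(system.file("cli", "segsel.R", package = "segsel"))')
Rscript $SEGSEL metrics --pred preds/ --truth masks/ --threshold 0.5 --pooling micro
Rscript $SEGSEL evaluate --matrix models.csv --criteria criteria.yaml --delta 0.5 --out report.csv
Rscript $SEGSEL reproduce      # computed vs printed benchmark scores
Rscript $SEGSEL dump-fixture --out table.csv
```

Masks are plain-text 0/1 grids or netpbm PBM/PGM; decision matrices are CSV
(first column = alternative id); criteria/weight configs are flat YAML or
CSV.

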