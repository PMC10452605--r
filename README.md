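# histofuse

Handcrafted–deep feature fusion for histopathology tile classification.

Histology tiles of colon and lung tissue are routinely sorted into five
classes — colon adenocarcinoma (ACAC), benign colon tissue (BTC), lung
adenocarcinoma (ACAL), benign lung tissue (BTL) and squamous cell
carcinoma of the lung (SCCL). `histofuse` implements a hybrid pipeline
for this task and makes every stage testable at desk scale without any
external dataset:

1. **Stain normalization** (Macenko-style). Transmitted light follows
   Beer–Lambert, `I_c = I0 · 10^(−Σ_s C_s M_{s,c})`; the 2×3 stain matrix
   `M` is estimated per tile from the SVD of the background-masked
   optical-density pixel cloud (extreme-angle selection at the 1%/99%
   percentiles), concentrations `C` are unmixed by least squares, rescaled
   to a reference tile's 99th-percentile stain maxima, and reconstructed
   through the reference stain matrix.
2. **GLPP texture descriptor.** Per pixel, the `P` neighbours on a circle
   of radius `r` are compared against the centre (`≥` → bit 1), read as a
   P-bit word clockwise and counterclockwise (the latter is the bit
   reversal of the former), and the larger decimal code is kept. Over the
   default schedule `(r,P) ∈ {(1,8), (2,16), (3,24)}` the per-scale code
   histograms (full bins for `P ≤ 12`, uniform-pattern bins above) are
   normalised and concatenated into one 300-dimensional vector.
3. **Depthwise-separable residual CNN with feature grafting.** Residual
   blocks of per-channel `k×k` convolutions plus 1×1 pointwise mixes
   (`k²C + C·Ct` weights vs `k²·C·Ct` standard); a custom layer broadcasts
   the GLPP vector across the spatial grid and appends it along channels,
   with the handcrafted branch held constant during backpropagation.
4. **Fused classification and evaluation.** Pooled network channels +
   GLPP vector feed an RBF SVM (C = 1), KNN (k = 5) or CART tree;
   reports include the confusion matrix and per-class/macro sensitivity,
   specificity, precision, F1 and one-vs-rest trapezoidal ROC AUC.
5. **Synthetic H&E generator.** Seeded Beer–Lambert rendering of
   elliptical nuclei with class-specific density and chromatin texture
   over an eosin-like stromal field, so stain recovery is a true
   parameter-recovery problem and the full pipeline runs offline.

See `vignettes/histofuse-methods.Rmd` for the model details, parameter
defaults and design decisions.

## Worked example

```r
library(histofuse)
library(dplyr)

spec  <- synthetic_spec(n_per_class = 20, tile_size = 96, seed = 42)
tiles <- generate_tiles(spec)
tiles
#> <tile_set> 100 tiles (96x96), 5 classes

ref <- estimate_stain_profile(tiles$tiles[[1]])
round(ref$stain_matrix, 3)
#>            R     G     B
#> stain1 0.592 0.758 0.273
#> stain2 0.066 0.992 0.106
```

The two rows are the recovered unit-norm stain vectors (hematoxylin-like
and eosin-like optical-density directions); on these rendered tiles they
sit within about a degree of the generator's ground truth
(`ground_truth_stains(spec)`).

```r
cfg <- pipeline_config(synthetic = spec,
                       train = train_config(epochs = 3, batch_size = 8),
                       seed = 42)
res <- run_pipeline(cfg, out_dir = file.path(tempdir(), "demo"))

res$model$history
#>   epoch train_loss train_acc val_loss val_acc
#> 1     1       2.59     0.157     1.73   0.133
#> 2     2       1.72     0.229     1.54   0.2
#> 3     3       1.55     0.286     1.35   0.667

glance(res$reports$svm_test)
#>   accuracy sensitivity specificity precision    f1   auc     n
#> 1        1           1           1         1     1     1    15
```

The network is only a feature extractor here (its softmax is far from
converged after three epochs), yet the fused representation — 128 pooled
network channels plus the 300-entry texture descriptor — lets the SVM
classify all 15 held-out tiles correctly. `tidy(res$reports$svm_test)`
gives the per-class table, `autoplot(res$reports$svm_test)` the confusion
heatmap, and every artifact (feature CSVs, model checkpoint + JSON
sidecar, reports, log) lands in the run directory.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/histofuse.R synth --out tiles/
Rscript inst/cli/histofuse.R run --config cfg.yaml --out runs/ --overwrite
```

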