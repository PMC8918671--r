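# spottype

Segmentation-free cell typing for single-molecule spatially resolved
transcriptomics (SRT) data, for anyone holding a decoded-spot table — one
mRNA molecule per row with a gene label and x/y coordinates in micrometers
(osmFISH, in situ sequencing, MERFISH and similar assays) — and a
cell-type signature matrix (cell types × genes, binary marker panels or
normalized scRNA-seq expression). Instead of segmenting cells and pooling
molecules per cell, `spottype` classifies tissue *locations* directly from
molecular density.

## Method

1. **Per-gene KDE.** For each gene, molecule positions are smoothed into a
   pixel image of local signal strength
   $d_g(x) = \sum_i w\,\exp(-\lVert x - p_{gi}\rVert^2 / 2\sigma^2)$,
   computed fast by snapping molecules to their closest pixel and
   accumulating a pre-computed Gaussian mass patch truncated at $2\sigma$
   (renormalized so each molecule contributes one unit of signal). Cost is
   exactly linear in the molecule count. An exact naive estimator
   (`naive_kde()`) is included as a verification oracle.
2. **Correlation typing.** Each pixel's expression vector is Pearson-
   correlated against every signature row; the pixel gets the
   best-correlating cell type. Pixels whose summed signal falls below the
   expression threshold are background.
3. **Quantification & preview.** Relative cell-type abundance over any
   rectangular view (classified pixels only), and a subsection preview that
   reproduces full-run pixels exactly away from the crop border, for cheap
   parameter optimization.

A synthetic tissue simulator with pixel-level ground truth
(`tissue_model()`, `simulate_spots()`) and benchmark dataset scaling
(`scale_dataset()`, 0.5×/2×/3×/5×) round out the package.

## Worked example

Simulate a small two-type tissue, write the two CSV inputs, and run the
pipeline:

```r
library(spottype)

sig <- as_signature_matrix(matrix(
  c(1, 0, 0.2,
    0, 1, 0.8), 2, 3, byrow = TRUE,
  dimnames = list(c("excitatory", "inhibitory"),
                  c("Slc17a7", "Gad1", "Snap25"))))
write_signatures(sig, "signatures.csv")

model <- tissue_model(sig = sig, n_cells = 80, depth = 20,
                      noise_fraction = 0.1, extent = c(0, 300, 0, 300),
                      radius = 10)
sim <- simulate_spots(model, seed = 7)
write_spots(sim$spots, "coords.csv")

cfg <- run_config("coords.csv", "signatures.csv",
                  width_px = 120, bandwidth = 10, threshold = 0.2,
                  out = "demo/out")
summary <- run_pipeline(cfg)
#> molecules: 1767 (1767 on shared gene panel of 3 genes)
#> grid: 120 x 120 px; foreground fraction: 0.205
#>   excitatory               1320 px   44.6%
#>   inhibitory               1638 px   55.4%
#>   background              11442 px
```

Reading the output: 1,767 simulated molecules were smoothed onto a
120 × 120 px grid (2.5 µm pixels); 20.5% of pixels exceeded the expression
threshold of 0.2 effective molecules per pixel and were typed, the rest is
background. Of the classified area, 44.6% correlates best with the
excitatory signature and 55.4% with the inhibitory one. On disk,
`demo/out_labels.tsv` holds the integer label matrix (−1 = background),
`demo/out_legend.csv` the cell-type/color legend, `demo/out_map.png` a
rendered map, `demo/out_density.tsv` the gene-summed density, and
`demo/out_abundance.csv` / `demo/out_config.yaml` the abundance table and
the exact parameters used.

The same pipeline is available from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","spottype.R",package="spottype"))') \
  run --coords coords.csv --signatures signatures.csv \
  --width 120 --bandwidth 10 --threshold 0.2 --out demo/out
```

(`preview --center X,Y [--size W,H]` runs the subsection preview,
`simulate` exposes the tissue generator.)

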