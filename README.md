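# cellograph

Per-cell scoring of perturbation responses in multi-condition single-cell
RNA-seq, using a semi-supervised graph convolutional network (GCN).

## What it does, and for whom

When an scRNA-seq experiment spans several conditions — drug vs control,
timepoints, treatment-and-withdrawal regimes — the per-sample label says where
a cell came from, not how strongly it responded. `cellograph` is for analysts
who want a *per-cell* answer: how prototypical is each cell of its
experimental condition, which cells sit in between conditions, and which genes
drive the separation.

Cells become nodes of a k-nearest-neighbor graph in PCA space. With adjacency
*A*, self-loops added (*Â = A + I*) and degrees *D̂*, the renormalized
operator *Ã = D̂⁻¹ᐟ²ÂD̂⁻¹ᐟ²* feeds a two-layer GCN:

    H⁽⁰⁾ = ReLU(Ã X W⁽⁰⁾)          latent embedding (cells × h)
    H⁽¹⁾ = softmax(Ã H⁽⁰⁾ W⁽¹⁾)     condition probabilities (cells × c)

Training is semi-supervised: only a small labeled subset (1–3% of cells per
condition) enters the cross-entropy loss; up to 200 epochs with early
stopping at patience 30 on validation loss. The outputs are:

* **condition probabilities** per cell (`H⁽¹⁾`) — the response score; cells
  with a probability ≥ 0.5 are assigned, the rest are flagged intermediate;
* **latent embedding** (`H⁽⁰⁾`) for k-means clustering and external 2-D
  visualization (PHATE/UMAP on the exported matrix);
* **gene ranking** from the first-layer weight matrix (one row per gene,
  aggregated and sorted; top 25 by default);
* **evaluation**: multiclass Brier score against ground truth and NMI
  benchmarking of clustering routes.

A negative-binomial synthetic-data generator with planted condition-specific
marker programs and an optional intermediate (mixed) population makes every
stage testable without downloads.

## Worked example

```r
library(cellograph)

# 3 conditions x 300 cells, 500 genes, 20 planted markers per condition,
# 20% of each condition drawn from an intermediate profile
d <- generate_multicondition_dataset(
  synthetic_spec(mixed_fraction = 0.2, seed = 42))

res <- run_pipeline(
  run_config(preprocess = preprocess_config(hvg = FALSE), seed = 42),
  expr = as_expression_matrix(d))
print(res)
#> cello_result: 900 cells, 500 genes, 3 conditions
#>   test accuracy 0.923 | Brier (all cells) 0.106 | assigned 98.3%
#>   best epoch 7 of 37 run

round(res$composition, 2)
#>        category
#> cluster cond1 cond2 cond3 unassigned
#>       1  0.03  0.06  0.87       0.04
#>       2  0.99  0.00  0.00       0.01
#>       3  0.05  0.95  0.00       0.00
```

Held-out cells are classified with 92% accuracy from 27 labeled cells, and
the latent k-means clusters align with the conditions. The probabilities
behave as designed: prototypical cells are confident while the planted
intermediate population is not —

```r
conf <- apply(res$probabilities, 1, max)
mean(conf[d$mixed_flag])    #> 0.765   intermediate cells
mean(conf[!d$mixed_flag])   #> 0.952   prototypical cells
```

and the planted markers dominate the gene ranking
(`rank_genes(res$model, method = "absolute")`).

Datasets round-trip through both standard containers
(`write_h5ad()`/`read_h5ad()`, `write_mtx_dataset()`/`read_mtx_dataset()`),
and `inst/cli/cellograph.R` wraps `simulate` and `run` for shell use.

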