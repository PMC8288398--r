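# isletAging

Aging leaves cell-type-specific fingerprints in the pancreatic islet:
old endocrine cells drift transcriptionally (cell-to-cell "noise"), and
β cells in particular accumulate an ER-stress / unfolded-protein-response
expression program. Detecting these signals in cross-sectional single-cell
RNA-seq is statistically delicate because age is a *donor-level* variable —
any per-cell comparison is confounded by donor batch effects.

`isletAging` is an R/Bioconductor-style package for this analysis. It is
aimed at computational biologists analysing UMI count matrices from islet
(or similar endocrine) scRNA-seq aging studies, and at methodologists who
want a fully simulatable testbed for donor-confounded designs. It provides:

* **Cell typing** — silhouette-selected k-means in PC space of highly
  variable genes, annotation from canonical hormone markers (GCG → α,
  INS → β, SST → δ, PPY → PP), and one-vs-rest Wilcoxon marker discovery.
* **Transcriptional noise** — per-cell distance to its (type, age-group)
  centroid over detected genes,
  `noise(c) = ||x_c − mean(group)|| / sqrt(#genes)`, compared old vs young
  with a Welch t-test; plus discovery of noise-correlated genes
  (Pearson r > 0.6, BH-FDR < 0.05).
* **The aging axis** — the core procedure: scan principal components of one
  cell type, orient each so old cells score higher, and select the
  highest-AUC component on which *every donor's* median score falls on its
  own age group's side of the between-group midpoint. Cells are then
  labelled old-like / young-like by that midpoint and aging-associated DEGs
  are called between the two states (Wilcoxon + BH-FDR, |log2FC| ≥ 0.5),
  with a direct old-vs-young contrast as cross-check. Types without a
  donor-consistent component are reported as not discriminated rather than
  forced.
* **Gene-set statistics** — set-score group tests (UPR branches, ERAD,
  apoptosis panels, ...), per-type fold-change matrices for curated lists,
  hypergeometric enrichment, and permutation GSEA for user-supplied sets.
* **Ligand–receptor interactions** — CellPhoneDB-style scoring (mean of the
  ligand's sender-type mean and the receptor's receiver-type mean) with an
  empirical cell-type-label permutation test and add-one p-values.
* **Regulatory hubs** — |Spearman| regulator→target networks over
  aging DEGs, top-decile edge retention, out-degree hub ranking.
* **A ground-truth simulator** — negative-binomial UMI counts over a
  16-donor, 5575-cell, four-type islet design with donor batch effects, a
  β-cell aging program, age-inflated overdispersion in α/β only, a planted
  ligand–receptor pair and a planted hub regulator, so every claim above is
  testable.

See `vignettes/islet-aging-methods.Rmd` for the statistical details and the
design decisions.

## Worked example

```r
library(isletAging)
library(SingleCellExperiment)

cfg <- simConfig()          # the default islet-aging study design
sce <- simulateIslets(cfg, seed = 1)
sce <- normalizeLog(qcFilter(sce)$sce)

# transcriptional noise, old vs young alpha cells
nv <- transcriptionalNoise(sce, "alpha")
str(compareNoise(nv))
#> $ cell_type : chr "alpha"
#> $ t         : num 23.2
#> $ p         : num 9.9e-109
#> $ mean_old  : num 1.45
#> $ mean_young: num 1.32
```

Old α cells are measurably noisier (mean deviation 1.45 vs 1.32 log2 units,
p ≈ 1e-108) because the simulation inflates their dispersion 1.5-fold —
the same qualitative pattern the method is designed to detect in tissue.
δ and PP cells, simulated without inflation, come out non-significant.

```r
res <- agingAxisDEGs(sce, "beta", seed = 1)
res$axis
#> AgingAxis for beta cells: PC 2 (orientation +1)
#>   old-vs-young AUC: 0.9347
#>   donor consistency: 16 of 16 donors
table(res$degs$direction)
#> down   up
#>   29   79
```

The β cells carry a planted 100-gene program (80 up, 20 down at
|log2FC| = 1); the selected component separates old from young cells with
AUC 0.93 consistently across all 16 donors, and the old-like vs young-like
contrast recovers 108 DEGs, almost all of them planted program genes.
`agingAxisDEGs(sce, "delta")` returns no axis: with no planted program a
donor-consistent component should not—and does not—exist.

The whole chain (QC → typing → noise → aging axis → signatures →
interactions → network) can also be run end-to-end from a config list or
YAML file:

```r
runPipeline(list(seed = 1, output_dir = "islet_run"))
pipelineReport("islet_run")
```

which writes per-stage TSVs plus a JSON run manifest.

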