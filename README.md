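# chimeraseq

Analysis of mixed-species RNA-seq from chimeric tissues — humanized mouse
livers in particular — for researchers working with xenograft models
whose samples contain human and mouse transcriptomes at once.

When reads are aligned to a combined human/mouse reference, every gene in
the count matrix carries a species tag, and the analysis must (i) decide
which species each droplet came from, (ii) type and zonate the cells of
each species, and (iii) quantify how humanized each cell compartment is.
`chimeraseq` implements this as a reproducible pipeline:

* **Species demultiplexing.** Per barcode, the number of distinct human
  genes (nHuman) and mouse genes (nMouse) with non-zero counts drives
  strict threshold rules: human iff `nHuman > 20·nMouse`, mouse iff
  `nMouse > 10·nHuman`, everything else *mixed* and excluded. QC
  (`>500` and `<5000` genes, `>1000` UMIs, strict) runs after
  restriction to the called species' cells and genes.
* **Normalization & imputation.** `ln(CPM/100 + 1)`, then adaptively
  thresholded low-rank imputation of dropout: rank-k approximation, each
  gene thresholded at the magnitude of its most negative approximated
  value, per-gene moment-matched rescaling, observed positives restored.
  The rank comes from singular-value spacings against a noise level
  (mean + 6·SD of the trailing spacings).
* **Clustering & markers.** PCA (50 components), shared-nearest-neighbor
  graph (k = 20, Jaccard weights), Louvain modularity clustering, and
  per-cluster Wilcoxon rank-sum markers (tie-corrected normal
  approximation, BH-adjusted within cluster).
* **Metagene annotation.** From an atlas DE table, each cell type's
  signature is its top-100, significant genes weighted by logFC; a
  cell's score is `S(M) = Σᵢ xᵢ·logFCᵢ`. Clusters take the argmax of
  mean z-scored scores (with an ambiguity margin); zone metagenes place
  hepatocyte/LSEC clusters into zones 1–3.
* **Humanization quantification.** Per-cell-type human fractions with
  Wilson 95% intervals; per-ortholog-pair human expression fractions
  from bulk CPM; composition comparison against a reference atlas
  (total-variation distance); and an albumin (ALB)-normalized
  fold-change summary reporting the fraction of a hepatocyte gene set
  at FC ≥ 2 and ≤ 0.5 between conditions.
* **Synthetic chimeras.** `simulate_chimera_sc()` generates
  ground-truthed droplet data (cell types in lineages, per-lineage human
  fractions, log-normal library sizes, multinomial counts, doublets,
  symmetric cross-species ambient contamination) plus matching reference
  DE tables, so every stage is testable against known truth.

## Worked example

Simulate a 2,000-droplet humanized liver, write it to disk in 10x-style
Matrix Market layout, and run the full pipeline:

```r
library(chimeraseq)

cfg   <- chimera_config(n_cells = 2000, seed = 1)
dir   <- tempfile()
paths <- write_chimera_dataset(cfg, dir)

pc  <- pipeline_config(input_dir = dir, reference = paths$reference,
                       zones = paths$zones, seed = 1)
res <- run_pipeline(pc, file.path(dir, "out"))

table(res$calls$label)
#> human mixed mouse
#>  1331    49   620

res$branches$human$clusters
#> cluster_assignment: 1331 cells in 14 clusters (modularity 0.867)

print(res$humanization, digits = 3)
#>    cell_type n_human n_mouse human_fraction ci_lo ci_hi one_sided
#> 1 hepatocyte    1046     108          0.906 0.888 0.922     FALSE
#> 2     immune      87     328          0.210 0.173 0.251     FALSE
#> 3       LSEC     198     184          0.518 0.468 0.568     FALSE
```

The mixed bin collects empty droplets, cross-species doublets and
heavily contaminated barcodes. The humanization report recovers the
simulated per-lineage human fractions (0.9 / 0.2 / 0.5 for hepatocytes,
immune cells and LSECs) within their Wilson intervals; every hepatocyte
cluster is additionally assigned a lobule zone (`labels_human.tsv` in
the output directory), and `manifest.json` records all parameters,
per-stage seeds and artifact hashes.

A thin command-line wrapper for the two entry points lives at
`inst/scripts/chimera-pipeline.R` (`simulate` and `run` subcommands).

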