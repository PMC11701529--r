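# clonetrace

Clonal barcode analysis for single-cell lineage tracing (scLT).

In an scLT experiment every profiled cell carries a heritable DNA barcode
identifying its clone of origin, next to its transcriptome or chromatin
profile. `clonetrace` takes the downstream path from a raw barcode–cell
assignment table to clone-level biology, for researchers analysing
barcoded differentiation experiments (e.g. lentivirally barcoded
hematopoietic stem and progenitor cells, HSPCs):

* **Barcode processing** — resolve multi-barcode cells with a dominance
  policy, filter multi-progenitor barcodes against initial-stage counts,
  compute detection rate / barcode diversity, clone sizes and per-type
  barcode statistics.
* **Fate outcomes and fate bias** — normalize each clone's cell counts to
  fate fractions, `value(β, A) = counts of barcode β in cell type A /
  counts of β in all cell types`, and call clone fate bias with a
  one-sided Fisher's exact test on the 2×2 occupancy table (clone in /
  out of a target cell-type set vs all other cells), with
  Benjamini–Hochberg FDR control across all clone × target tests
  (biased at FDR < 0.05, odds ratio > 1).
* **Lineage relationships** — Spearman correlation of barcode signatures
  between every pair of cell types, plus an average-linkage dendrogram on
  `1 − ρ` written as Newick.
* **Fate-linked differential testing** — negative-binomial GLM
  likelihood-ratio tests (RNA) or exact/tie-corrected Wilcoxon rank-sum
  tests (ATAC) between cells whose clones took different fates;
  significant at `p < 0.05` and `|log2FC| > 0.5`.
* **Motif analysis** — PWM scanning with an exact dynamic-programming
  score-distribution threshold at a match p-value cutoff (default 5e−5)
  and hypergeometric foreground-vs-background motif enrichment.
* **Synthetic experiments** — `simulate_experiment()` generates complete
  experiments (assignments, metadata, clone matrix, counts, peaks,
  motifs) with a planted ground-truth ledger, so every stage above is
  testable end to end.

## Worked example

Simulate a 500-clone experiment, resolve barcodes, and run the fate
analysis:

```r
library(clonetrace)

ex <- simulate_experiment(sim_config(n_clones = 500, n_genes = 0,
                                     n_de_genes = 0, n_motifs = 0,
                                     seed = 20))
resolved <- resolve_barcodes(ex$assignments)
quality_summary(ex$cells, resolved)
#> quality_summary: 2374 cells, 1922 barcoded (detection rate 0.810),
#> 484 unique barcodes

cm <- filter_high_confidence(ex$clone_matrix,
                             ex$initial_counts[rownames(ex$clone_matrix)])
head(clone_sizes(cm), 3)
#>     clone_id size n_cell_types
#> 1 clone_0169   35            7
#> 2 clone_0031   27            5
#> 3 clone_0470   27            7

fb <- clone_fate_bias(cm)
fb
#> fate_bias: 460 clones, 7 targets, 44 biased at FDR < 0.05
head(summarize_fate_bias(fb), 3)
#>         label n_clones   fraction
#> 1    balanced      333 0.72391304
#> 2    untested       83 0.18043478
#> 3 Baso biased       10 0.02173913

lc <- lineage_relationship(cm)
lineage_tree(lc)
#> "(DC:0.77,(Ery:0.74,(Lymphoid:0.73,(Mono:0.71,(Neu:0.67,
#>  (HSPC:0.58,Baso:0.58):0.09):0.05):0.02):0.01):0.03);"  # abridged
```

Reading this output: 81% of cells had a resolvable barcode (the
configured dropout was 0.8); 44 of 460 clones show significant fate bias
at FDR < 0.05 (the simulation planted 30% biased clones, most of them too
small to reach significance — single cells are reported `untested`);
branch lengths in the Newick tree are `1 − ρ` merge heights, so the
shallow HSPC/Baso pair is the most clonally coupled.

`run_report(cm, "out/")` writes the whole table set (clone sizes, barcode
statistics, fate map, fate-bias calls and summary, lineage correlation
and tree) in one call, and
`system.file("exec", "clonetrace", package = "clonetrace")` is a shell
wrapper with `simulate` / `barcodes` / `fate` / `lineage` / `diff` /
`motif` / `report` subcommands over the same functions.

See the vignette (`vignettes/clonal-fate-analysis.Rmd`) for the models,
parameter meanings, and design choices.

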