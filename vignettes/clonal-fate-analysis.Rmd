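---
title: "Clonal fate analysis for single-cell lineage tracing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal fate analysis for single-cell lineage tracing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrace)
```

## The problem

Single-cell lineage tracing (scLT) couples a heritable DNA barcode — read
out alongside a transcriptome or chromatin profile — to every cell, so that
cells sharing a barcode can be recognised as a *clone*: the presumed
descendants of one progenitor. Given a table of barcode-cell assignments
and per-cell annotations, the questions this package answers are the
standard ones of clonal analysis in, for example, barcoded hematopoiesis
experiments:

* How large is each clone, and in which cell types was it observed?
* Which clones are *fate biased* — over-represented in one cell type
  relative to random sampling of all barcoded cells?
* Which cell types share clonal origins (*lineage relationships*)?
* What distinguishes the molecular state of progenitors whose clones take
  different fates (differential expression / accessibility, motifs)?

Everything operates on one central object, the **clone matrix**: an
integer matrix of cell counts with one row per clone and one column per
cell type (or any other grouping label, such as time point). Its rows are
the clone's "barcode signature".

## From raw assignments to clones

One cell should carry one lineage barcode, but sequencing error and
ambient barcodes attach several barcodes to some cell indexes.
`resolve_barcodes()` applies a dominance policy: a multi-barcode cell is
kept only when its top barcode count is at least `min_dominance` (default
2) times the runner-up and at least `min_count` (default 1); otherwise the
cell is dropped. The published studies this mirrors each used their own
ad-hoc rule; we chose a single explicit, parameterized policy so results
are reproducible from the raw assignment table alone. Ties at the top
fail dominance (unless `min_dominance = 1`, where the lexicographically
smallest barcode wins — a deterministic tie-break we apply after every
primary sort key throughout the package).

Barcodes that labelled more than one cell at the *initial* barcoding
stage cannot mark a single progenitor's descendants.
`filter_high_confidence()` removes clones whose initial-stage cell count
exceeds `max_initial_cells` (default 1). Filtering deliberately requires
explicit initial-stage counts: a large clone at a late time point is
indistinguishable from a multi-progenitor barcode without that evidence,
so no heuristic inference is attempted.

`quality_summary()` reports the barcode detection rate (barcoded /
assayed cells) and unique barcode count, the two parameters that determine
the resolution and robustness of an scLT experiment.

## Fate outcomes and fate bias

`fate_mapping()` normalizes each clone row to fractions:

$$\mathrm{value}_{\beta A} = \frac{\text{counts of barcode } \beta
\text{ in cell type } A}{\text{counts of barcode } \beta \text{ in all
cell types}},$$

so each row is a point on the simplex (the clone's fate outcome).

`clone_fate_bias()` tests, for every clone $\beta$ and target cell-type
set $T$, the 2×2 table

|              | in $T$ | not in $T$ |
|--------------|--------|------------|
| clone        | $a$    | $b$        |
| other clones | $c$    | $d$        |

with a one-sided Fisher's exact test: $p = P(X \ge a)$ for
$X \sim \mathrm{Hypergeom}(N = a{+}b{+}c{+}d,\, K = a{+}c,\, n = a{+}b)$.
The paper trail behind this statistic specifies only "Fisher's exact
test"; we use the enrichment (greater) side because fate bias is an
over-occupancy question, and expose `alternative = "two.sided"` for users
who want the symmetric test. All clone × target p-values are adjusted
jointly by Benjamini–Hochberg (the universe is not stratified by target,
since a clone competes against every possible fate; per-target
stratification is available via `stratify_by_target`). A clone is labelled
`"<target> biased"` by its minimum-FDR significant enriched test at
`fdr < alpha` (default 0.05) with odds ratio > 1, `"balanced"` otherwise.
Clones passing several targets are labelled by the minimum-FDR one (ties:
larger $a$, then lexicographic target); the full significant set is kept
in the result for multi-label use. Clones below `min_clone_size = 2`
cells are reported `"untested"` — one cell cannot evidence bias.

Target sets default to one singleton per cell type; named lineage
groupings (e.g. `list(Lymphoid = c("T", "B", "NK"))`) pool columns before
testing. `summarize_fate_bias()` reports label fractions either
clone-weighted or cell-weighted — published fate-bias summaries do not
always state which weighting they use, so both are first-class.

## Lineage relationships

`lineage_relationship()` computes the Spearman correlation of barcode
signatures between each pair of cell types, over clones. Two
interpretive choices were genuinely open and are exposed as options
rather than silently fixed:

* **Signature**: raw per-clone counts (default) or fate-map fractions.
  Because Spearman works on ranks the two are nearly equivalent; counts
  are the default as the more primitive quantity.
* **Clone universe**: for each pair, clones absent from *both* members
  carry no ordering information and are excluded (`universe =
  "pairwise"`, default); `"global"` keeps the full clone set, which
  shrinks all correlations toward the shared-absence pattern.

Constant signature vectors have no rank ordering; their correlation is
defined as 0 with a warning. `lineage_tree()` clusters cell types on the
distance $1 - \rho$ with average linkage (complete/single available) and
returns a Newick string; two labels give `(A:h,B:h);` with
$h = (1-\rho)/2$.

## Fate-linked differential testing

`fate_bias_diff()` partitions the cells of one cell type by their clone's
fate-bias label and tests each feature between the two groups:

* **RNA** (`nb_test()`): negative-binomial regression of counts on the
  group indicator with a log library-size offset, dispersion estimated by
  maximum likelihood per gene (`MASS::glm.nb`, iterating from a
  moments-style start), and a likelihood-ratio test against the
  intercept-only model. When the dispersion estimate diverges the test
  falls back to the Poisson GLM LRT, its small-dispersion limit. We
  define this explicit NB-LRT rather than delegating to a third-party
  marker-test wrapper so the procedure is fully specified, accepting
  small numeric divergence from such tools.
* **ATAC** (`wilcoxon_test()`): two-sided rank-sum test, exact by
  enumeration of all $\binom{n}{n_a}$ group assignments of the pooled
  average ranks when $n_a + n_b \le 12$ (the enumeration handles ties
  exactly, which classical exact tables do not), normal approximation
  with tie and continuity corrections otherwise.

Features with raw $p < 0.05$ and $|\log_2\mathrm{FC}| > 0.5$ are flagged
significant — deliberately the raw p-value, matching common practice for
this analysis; a BH column is emitted additionally. Fold changes use a
pseudocount of 1 on normalized group means; library sizes are normalized
as per-cell total over the median total. One consequence worth knowing:
strongly one-directional DE panels shift total counts and can bias fold
changes of null features (ordinary compositional bias of total-count
normalization).

## Motif scanning and enrichment

`pwm_score_threshold()` computes the *exact* null distribution of the
PWM log-odds score under a 0-order background by dynamic programming over
motif positions, after discretizing scores to a grain of $10^{-3}$
log-odds units and adding a pseudocount of 0.008 to the motif
probabilities (both documented constants, configurable). The match
threshold is the smallest score whose tail probability is at most
`p_cutoff` (default $5 \times 10^{-5}$). A consequence users should
expect: a length-4 motif's perfect match has background probability
$(1/4)^4 = 3.9 \times 10^{-3}$, so at the default cutoff *no* window can
match — short motifs are simply uninformative at that stringency.

`scan_regions()` applies best-window, any-hit semantics on both strands
(reverse strand via the reverse-complemented PWM; windows containing `N`
never match); the background is estimated from the scanned sequences
(with add-one smoothing so log-odds stay finite) or set to uniform.
`motif_enrichment()` compares match counts between disjoint foreground
and background region sets with the same one-sided hypergeometric test
used for fate bias, BH-adjusted across motifs; the enrichment score is
the log2 ratio of smoothed match rates $(m + 0.5)/(n + 1)$, which is
exactly 0 at equal observed rates. GC-matched backgrounds and k-mer
shuffling nulls are out of scope.

## The synthetic experiment generator

`simulate_experiment()` emulates a lentiviral-barcoding experiment in
hematopoiesis: clones seeded in an HSPC pool, propagated multinomially
into seven cell types, with detection dropout and noise. Defaults are
fixed at the demonstration scale — 2,000 clones (about 10,000 cells),
background proportions HSPC 0.40, Mono 0.15, Neu 0.15, Ery 0.10,
Lymphoid 0.10, Baso 0.05, DC 0.05, log-normal clone sizes (meanlog 1.3,
sdlog 0.8; mean ≈ 5 cells), 30% of clones biased with target occupancy
0.8, detection rate 0.8, 5% multi-barcode cells, 5% multi-progenitor
barcodes, a 200-gene panel with 20 genes at $|\log_2\mathrm{FC}| = 2$
(NB dispersion 0.5) planted between the two largest bias groups, and a
motif benchmark planting one 8-bp motif's consensus in 80% of foreground
vs 10% of background regions. All randomness derives from one mandatory
integer seed via per-stage substreams, so each stage is independently
reproducible and reruns are byte-identical.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: barcode sequencing error structure (assignments
are taken as given), realistic transcriptome topology beyond group-mean
shifts (no embedding structure, no pseudo-time), cell-type annotation
error, batch effects, or GC composition of real peaks. Recovery results
on it demonstrate correctness of the statistics under the stated model,
not performance guarantees on any particular experimental platform.

Test suites and the acceptance script run the same generator at reduced
clone counts (40–1,500 clones depending on the check, with replicate
counts chosen to give tight binomial error on each rate); these problem
sizes are the package's own benchmark choices and are stated in the test
files alongside each check.

## Numerical and degenerate-input choices

* Category order is first-appearance order of the input everywhere, and
  every output table has a fixed column order with floats at 6
  significant digits, so reruns are bit-reproducible.
* All-zero clone rows are dropped at read/construction time with a
  warning; a clone matrix therefore never has a zero row and fate-map
  rows are always defined.
* The sample odds ratio $ad/bc$ is reported with the conventional
  $\infty$ when $bc = 0, ad > 0$, and 0 when $ad = 0, bc > 0$.
* `initial_counts` must cover exactly the clones in the matrix —
  supplying counts for unknown clones is an error, because it usually
  means the matrix and the initial-stage table came from different runs;
  subset with `initial_counts[rownames(cm)]` when the initial stage saw
  clones that were never re-detected.
* An all-zero feature in both differential groups reports $p = 1$,
  $\log_2\mathrm{FC} = 0$ and is never significant.
* $-\log_{10} p$ is capped at 300 in volcano tables.

## A minimal session

```{r example}
cm <- clone_matrix(matrix(c(18L, 2L, 0L, 3L, 3L, 2L, 1L, 8L, 9L), 3,
                          byrow = TRUE,
                          dimnames = list(c("c1", "c2", "c3"),
                                          c("HSPC", "Mono", "Ery"))))
clone_sizes(cm)
round(fate_mapping(cm), 3)
fb <- clone_fate_bias(cm)
fb$calls[, c("clone_id", "label", "odds_ratio", "p_value", "fdr")]
```

## Interfaces

The exported functions are the primary interface; `run_report()` executes
the whole clone-matrix workflow (sizes, barcode statistics, fate map,
fate-bias calls and summary, lineage correlation and Newick tree, plus
the differential table when expression data are supplied) into a
directory of TSVs, removing partial output on failure. A thin shell
wrapper with subcommands (`simulate`, `barcodes`, `fate`, `lineage`,
`diff`, `motif`, `report`) is installed under
`system.file("exec", "clonetrace", package = "clonetrace")` for users who
drive the workflow from scripts.

## Known limitations

* Barcode extraction and error correction from reads is upstream and out
  of scope; the pipeline starts at the assignment table.
* The fate-bias test treats cells as exchangeable draws; it does not
  model overdispersion between sister cells of a clone beyond what the
  2×2 conditioning absorbs.
* The NB test is per-gene with no information sharing across genes
  (no empirical-Bayes dispersion shrinkage); at very small group sizes
  its power is accordingly limited.
* Peak-to-gene annotation, GO enrichment and phylogenetic reconstruction
  from editing-based barcodes are intentionally not implemented.
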