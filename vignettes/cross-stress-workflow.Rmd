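---
title: "Cross-stress overlap analysis of Fe- and Pi-deficiency transcriptomes"
author: "FePiOverlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-stress overlap analysis of Fe- and Pi-deficiency transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FePiOverlap)
```

# The analysis

Iron deficiency and phosphate starvation trigger partly antagonistic
transcriptional programs in Arabidopsis roots: Pi starvation represses
the strategy-I iron-acquisition machinery (FRO2, IRT1 and the FIT
regulon) that Fe deficiency induces. A standard way to study this
cross-talk is to take the differentially expressed gene (DEG) lists of
the two stresses, intersect them, and dissect the overlap from several
angles:

1. **Fold changes with an undetermined-control convention.** For each
   overlap gene, the fold change in a contrast is the mean ± sample SD
   of the per-replicate treatment/control abundance ratios (RPKM-like
   units, replicate *i* paired with replicate *i*). When every control
   replicate has zero reads but the treatment is expressed, no ratio
   exists; the fold is reported as *undetermined* and rendered "-" in
   tables. These genes behave as strongly up-regulated and are kept by
   any up-regulation cutoff.
2. **Fold-cutoff filtering.** A gene is retained at cutoff *c* (> 1)
   when its mean fold in at least one contrast is ≥ *c* or ≤ 1/*c*;
   the conventional operating points are 2 (the main filter) and 1.5
   (the promoter-analysis subset).
3. **Four regulatory types.** Each overlap gene falls into one of four
   direction pairs: down/down (type 1), up/up (type 2), Pi-up & Fe-down
   (type 3), Fe-up & Pi-down (type 4). Type 4 — induced by Fe
   deficiency, repressed by Pi starvation — is the biologically loaded
   class, as it contains the Fe-acquisition genes that Pi starvation
   turns off.
4. **Hierarchical clustering** of the log2 fold-change profiles of the
   filtered genes (undetermined folds become missing cells).
5. **Co-expression modules.** Genes are correlated across a normalized
   root-array compendium; pairs with Pearson *r* ≥ 0.7 form edges of an
   undirected network, and a *module* is a connected component — a
   cluster with no edge to any other cluster.
6. **GO over-representation with elim.** Classic one-sided
   hypergeometric tests per term, decorrelated by the elim algorithm:
   specific terms are tested first and, when significant at the cutoff
   (0.01), their genes are removed from all ancestors before those are
   tested.
7. **P1BS promoter scanning.** The PHR1 binding site is the imperfect
   palindrome GNATATNC. Fixed-length upstream sequences (3000 bp before
   the translation start) are scanned for the degenerate element, and
   hits are summarized by gene, by proximal occurrence (within 1000
   bp), and by concrete matched 8-mer.

`runPipeline()` executes the stages in this order on synthetic inputs
with known ground truth and writes every artifact plus a JSON report.

# Conventions and numerical choices

**Replicate pairing and partial zeros.** Replicates are paired by
index; the analysis declares this rather than guessing a design.
When some but not all control replicates are zero, the affected pairs
are dropped and `n` reduced — this keeps the mean/SD finite while
reserving the undetermined flag for the all-zero case. A gene silent
in both conditions gets a distinct `"silent"` flag.

**Exact ties.** A mean fold of exactly 1 carries no direction; such
genes are left UNCLASSIFIED instead of being silently assigned to a
type. On continuous data this is a measure-zero event.

**Two readings of the per-type sub-counts.** "N genes of a type changed
beyond *c*-fold" can mean beyond the cutoff in *either* contrast or in
*both*. Both readings are reported (`classifyTypes()$subCounts`) and
neither is asserted as canonical.

**Clustering choices.** The distance is 1 − Pearson correlation across
the contrast columns with average linkage: the standard
expression-heatmap choice, grouping genes by profile shape. With only
two contrasts the correlation degenerates to ±1, which still splits
concordant from discordant profiles; Euclidean distance is available
for a magnitude-sensitive tree. Missing cells are handled
pairwise-complete; profile pairs sharing fewer than two finite cells
get the maximum correlation distance (2), and genes with all-missing
profiles are excluded and reported. Input genes are sorted
lexicographically before agglomeration so merge-distance ties resolve
identically regardless of input order, making the leaf order
reproducible.

**Network choices.** The threshold is applied inclusively (≥ 0.7) to
the *signed* correlation: only positive co-expression forms edges,
which is the convention of this class of co-expression networks; an
absolute-value mode is available behind a flag. Zero-variance profiles
have no defined correlation and are excluded with a warning rather
than failing the run. The network is built only among the supplied
gene list, not against the whole compendium.

**elim details.** Terms are processed most-specific-first, ordered by
the *longest* path to the root (deepest first, ties by term id). Each
term is tested on its current — possibly pruned — gene sets; the
classic p-value is computed on the unpruned sets and reported
alongside. The significance threshold used for pruning equals the
conventional reporting cutoff (0.01) but is a separate argument. With
cutoff 0 no pruning occurs and elim reduces to classic Fisher, which
is both a sanity property and a test oracle. `part_of` edges are
treated like `is_a` for ancestry (configurable). Raw p-values are
reported; no multiple-testing correction is applied, matching how elim
results are conventionally tabulated.

**Promoter coordinates.** Position 1 is the base immediately 5′ of the
translation start. For a length-*L* promoter string whose last base is
adjacent to the start, a window starting at string position *s* with
pattern length *m* is reported at near distance `L − s − m + 2` and far
distance `L − s + 1`. This is the convention under which a published
P1BS survey's "within −1000 bp" gene count is reproduced from its own
printed positions; it is an inference from internal consistency, stated
as such. Scanning is forward-strand only: GNATATNC equals its own
reverse complement at the degenerate level, so a second-strand scan
adds no hits (asserted as a test). Duplicate identical hit records are
preserved, because published tallies count them. A masked base (`N`) in
a promoter never matches any pattern position.

# What the synthetic generators emulate

Every input class has a generator whose planted truth the tests
recover:

* `genContrastExperiment()` — two replicate tables with planted DEGs.
  Fold effects are log-normal (symmetric in log space; `sdlog = 0.7`
  by default, so roughly a quarter to a third of planted DEGs exceed
  twofold while the tail still produces occasional very large folds,
  echoing the shape of published cross-stress fold tables). Replicate
  noise is multiplicative log-normal with unit mean at CV 0.1, a
  typical biological-replicate spread; with `noiseCv = 0` the planted
  folds are recovered exactly. Three percent of planted genes are
  emitted with all-zero controls (about the rate at which "-" rows
  appear in printed fold tables) to exercise the undetermined
  convention.
* `genCompendium()` — module genes share a latent array profile with
  weight *w* plus noise of SD *σ*, giving expected within-module
  Pearson correlation *w²/(w² + σ²)* in closed form; the default
  (*w* = 3, *σ* = 1) plants modules at r = 0.9, comfortably above the
  0.7 threshold, over 200–300 arrays.
* `genGoUniverse()` — a random rooted DAG of bounded depth with
  *unpropagated* direct annotations and a study list enriched for one
  planted term by weighted sampling at stated odds (odds 1 is the
  hypergeometric null). The planted term is kept childless so that its
  propagated annotation set is exactly its carriers plus direct
  background — a clean ground truth that a correct enrichment engine
  should rank first.
* `genPromoters()` — background sequence at 36% GC (Arabidopsis
  promoter-like) with concrete motif instances planted at exact
  upstream distances; `forbidBackgroundHits` removes all other
  occurrences of the degenerate pattern by targeted resampling, so a
  scan must return exactly the planted truth.

Determinism is part of the contract: one integer seed drives one
generator stream per artifact, and identical seeds reproduce outputs
byte for byte.

What the generators do **not** emulate: read-level sequencing noise
and library-size effects, array batch structure, realistic GO topology
or annotation bias, genome-scale promoter composition, and the
correlation structure of real regulons. Passing the planted-truth
tests therefore demonstrates that the *operations* are correct, not
that any biological conclusion transfers; on real data the published
network/enrichment outputs additionally depend on the exact compendium
curation and annotation release used, which is why those figures are
checked here through planted-truth substitutes rather than
reproduction.

# Problem sizes

The packaged runs are desk-scale by design: pipeline defaults use a
1500-gene universe with 300 planted DEGs per contrast (120 shared),
three replicates, a 200-array compendium with two planted modules, a
40-term ontology over the overlap genes, and one promoter per scanned
gene. The test suite and the acceptance script use the same or smaller
sizes, with recovery rates measured over 50–100 seeds. All constants
of the analysis itself (cutoffs 2 and 1.5, threshold 0.7, elim cutoff
0.01, GNATATNC, 3000 bp, 1000 bp) are the published operating points
and are carried in `pipelineConfig()`.

# A worked fragment

```{r example}
ot <- readOverlapTable(system.file("extdata",
    "table1_printed_foldchanges.tsv", package = "FePiOverlap"))
ot
cls <- classifyTypes(ot, cutoffs = c(2, 1.5))
cls$counts

hits <- readMotifHits(system.file("extdata", "table3_p1bs_hits.tsv",
    package = "FePiOverlap"))
summarizeHits(hits, within = 1000)[1:4]
```

The packaged fold-change table is the 110-row excerpt printed in the
article body of a published cross-stress survey (its complete
137/579-gene tables are distributed as journal supplementary files and
are not packaged); the hit table is the printed 18-record P1BS survey,
including its duplicated record, which the summary deliberately counts
twice.

# Interfaces

The package is an analysis library: the exported functions, this
vignette and `scripts/acceptance.R` are the interface, with
`runPipeline()` as the single-call entry point; R users drive it from
R rather than a shell, so no separate command-line binary is shipped.
Stage artifacts are plain text (TSV, OBO 1.2, FASTA, SIF/GraphML,
Newick, JSON) so runs are diffable and auditable.

# Known limitations

* With two contrasts the correlation distance for clustering is
  degenerate (±1); it is kept as the default for fidelity to
  expression-heatmap practice, with Euclidean as the alternative.
* The elim implementation covers the elim decorrelation only; other
  decorrelation schemes (weight, parent-child) are out of scope.
* The OBO parser reads the minimal subset (`[Term]`, `id`, `name`,
  `namespace`, `is_a`, `relationship: part_of`, `is_obsolete`) that
  the workflow needs, not the full OBO 1.4 grammar.
* Exact degenerate matching only — no position weight matrices or
  mismatch tolerance in the promoter scan.
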