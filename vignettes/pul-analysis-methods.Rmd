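---
title: "Methods: PUL composition, synteny and diversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PUL composition, synteny and diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulscape)
```

## The model

A polysaccharide utilization locus (PUL) is, operationally, a run of
co-located genes anchored on a susC/susD transporter pair — a susC and a
susD gene at consecutive positions on the same DNA strand — together with
the degradative genes around it. pulscape works entirely at the level of
*gene order and annotation*: a genome is a sequence of categorized genes
(susC, susD, GH/PL/CE with a family or subfamily label, sulfatase,
peptidase, phosphodiesterase, regulator, other) ranked by a 1-based
ordinal along each replicon. Base-pair coordinates are deliberately not
used: every quantity downstream — locus membership, composition, synteny —
depends only on order and adjacency, so the ordinal abstraction loses
nothing and makes the pipeline independent of any particular annotation
format.

The analysis assumes the input annotation is trustworthy: susC/susD and
family calls are taken as given, and no sequence-level inference is
attempted. Subfamily resolution is carried only for GH5, GH13, GH30 and
GH43, the four large multifunctional families where subfamilies track
substrate specificity; a subfamily suffix on any other family is a
validation error rather than a silently accepted label. Sulfatases and
peptidases are biologically relevant PUL components but are not resolved
into families; they collapse to the two broad features `Sulf` and `Pept`.

## Locus detection and sorting

Anchor finding merges maximal alternating same-strand runs
(C,D,C,D,...) into a single multi-pair anchor; two or more pairs define a
tandem-repeat (trsusCD) locus. Pairs are accepted in either textual
order, because a reverse-strand locus appears D-then-C in a
position-sorted table. susC/D genes that form no pair (an intervening
gene, opposite strands, or a lone gene) seed loci that classify as
`REJECTED`; orphan sus genes within the extension gap of one another are
merged into one seed so that a susC–x–susD arrangement is one rejected
locus, not two.

Locus boundaries extend outward from each seed over degradative genes
(GH/PL/CE, sulfatase, peptidase), bridging at most `max_gap` consecutive
non-degradative genes (default 2). Upstream locus predictors use
empirically calibrated intergenic distances for this step; since inputs
to this package normally arrive pre-delimited, the order-based rule is a
reproducible stand-in and `max_gap` is exposed as a parameter. When two
seeds could claim the same gene, each contested gene goes to the nearer
seed core and an exact midpoint goes to the upstream seed — a
deterministic rule, applied after computing each seed's unconstrained
extension so that a distant seed can never silently truncate a locus it
could not actually reach.

Tandem loci that encode CAZymes are kept in the composition analysis
(flagged, so tandem-specific statistics can still find them); runs of
CAZyme genes with no susC/D seed at all are classified
`CAZYME_CLUSTER_NO_SUSCD` through a separate entry path and excluded from
the core PUL statistics.

## Composition, uniqueness, clustering

A PUL's composition is the set of its degradative feature labels;
copy-aware mode keeps per-feature gene counts instead. Unique PULs are
equivalence classes under exact equality — groups (≥ 2 members) plus
singletons. Group keys are canonical sorted feature strings, so outputs
are stable across runs and row orders.

Between-composition dissimilarity is the Jaccard distance on feature
sets, computed with `vegan::vegdist`; copy-aware mode uses the
quantitative form, which equals the Ruzicka weighted Jaccard
`1 − Σ min / Σ max`. Trees are average-linkage (`stats::hclust`,
UPGMA), and clusters at mismatch threshold *t* are subtrees with merge
heights ≤ *t*/100, inclusive, so the 0% cut coincides exactly with
exact-equality grouping. Clustering operates on the deduplicated set of
unique compositions and membership maps back to every PUL afterwards;
with exact duplicates the UPGMA tree is equivalent either way, and the
deduplicated route makes the cluster counts the counts *of unique PULs*,
which is the quantity of interest. The copy-aware clustering mode is an
extension beyond exact-equality copy-aware uniqueness and is labelled as
such.

Two numerical choices matter here. First, the cut adds a tolerance of
1e-9 to the threshold height so that merges at exactly the cut height are
included despite floating-point error. Second, the cut itself is
implemented as a union-find pass over the merge list rather than
`stats::cutree`, because average-linkage heights can carry epsilon-scale
inversions that make `cutree` reject the tree outright; the union-find
cut is verified against `cutree` on clean trees in the test suite.
Tie-breaking between equal-height merges follows `hclust`'s deterministic
order, so results are reproducible, but partitions at a cut that falls
on tied heights can depend on input order (cluster *counts* do not, in
every case the tests exercise).

## Synteny

Gene order is compared within clusters of identical composition. Each
retained gene (CAZymes, sulfatases, peptidases, susC, susD, regulators —
everything else is ignored) contributes one symbol, genes of the same
family share a symbol, and susC and susD always get distinct symbols.
Similarity between two encoded strings is
`1 − d_OSA / max(length)`, with `d_OSA` the optimal string alignment
(restricted Damerau–Levenshtein) distance: unit-cost substitutions,
insertions, deletions and adjacent transpositions. The transposition
operation is what makes a simple swap of two adjacent genes cost 1
rather than 2, which is the behavior a gene-order comparison wants.

Gene order is strand-relative, and stored order reflects the sequencing
direction, not the biological one. The default therefore compares both
orientations and keeps the larger similarity; a strict mode compares
strings as stored. Cluster-level conservation is the median over all
C(k,2) pairs; a singleton cluster has no pairs and reports `NA`. When
genome metadata is available each pair is annotated with its taxonomic
span (same genus, same class, across classes), since order conservation
is expected to decay with taxonomic distance. The retained-category set
includes only susC/susD among transporters; generic transporter
annotations, if present, fall into `other` and are ignored.

## Contingency statistics

Family enrichment in or out of PULs uses gene-level 2×2 tables: genes of
one feature versus genes of all other degradative features, inside versus
outside PULs. Counting genes (not loci) matches the question "is this
family's gene complement concentrated in PULs?" and gives the tests their
sample size. Each cell's adjusted standardized residual is

(O − E) / sqrt(E · (1 − RowMarginal/n) · (1 − ColumnMarginal/n)),

approximately standard normal under homogeneity, positive when the cell
is over-represented. For any 2×2 table the squared residual equals the
Pearson χ² statistic — an identity the tests verify to 1e-9 against the
package's own χ² wrapper and against `chisq.test`'s `stdres`, keeping the
implementation and its cross-check separate. χ² tests use no continuity
correction; expected counts below 5 trigger a warning, not a switch to an
exact test. Across-feature scans attach Benjamini–Hochberg q-values as a
clearly labelled extension; raw p-values are always reported.

Medians get confidence intervals by inversion of the one-sample Wilcoxon
signed-rank test (the Hodges–Lehmann construction in
`stats::wilcox.test`); a constant sample short-circuits to a zero-width
interval, since the test itself is undefined there. Even-length medians
are the mean of the central pair throughout.

## Rarefaction

Diversity saturation is estimated by drawing genome subsamples *without
replacement* — required for the curve to reach the full data set at full
sample size — pooling their PULs and counting unique PULs (or clusters at
a mismatch threshold), with 10 replicates per size and medians fitted by
an ordinary least-squares quadratic. The default size grid is ~15
log-spaced values from 1 to the genome count, denser where the curve
bends. One master seed spawns an independent substream per
(size, replicate) cell, so curves are bit-identical across runs and
independent of evaluation order. Quadratic extrapolation beyond the
fitted range is flagged as such; it is a trend summary, not a richness
estimator, and no Chao-type correction is attempted.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of a susC/D-locus corpus
with known ground truth. Its defaults encode the corpus-scale rates the
pipeline should encounter: 10.7% of loci carry broken anchors, 3.3%
tandem anchors, half of the anchored loci lack CAZymes, and archetype
sizes follow a shifted Poisson (1 + Pois(2.7)) putting the median number
of families per PUL near 3.5. Archetype abundances are geometric, so a
few compositions recur very frequently while most are rare. Gene
duplication is modelled as an *archetype-level* propensity (each family
duplication-prone with probability 0.13, prone families carried in two,
rarely three, copies by every locus of that archetype) plus a small
per-locus deviation (1.5% per family): duplication patterns are largely
inherited, and modelling them as independent per-locus coin flips would
fragment copy-aware groups far beyond what a real corpus shows. Under
these defaults roughly 40% of PULs carry a duplicated family and
copy-aware uniqueness exceeds presence uniqueness by ~30%.

Composition noise (family swap, family drop) and gene-order shuffling
are separate dials, each traced in the ground-truth table, so recovery
tests can assert exact fixed points: with all noise off, the classifier
reproduces every expected class, clustering at 0% returns exactly the
configured number of archetypes with purity 1.0, and conserved-order
clusters score median synteny 1.0.

What the generator does *not* emulate: assembly fragmentation (loci
split across scaffolds), annotation error in the category calls,
isofunctional families, real taxonomic correlation structure beyond a
small genus pool, and intergenic-distance variation (the gene-ordinal
abstraction has none). Passing recovery tests therefore demonstrates
correctness of the pipeline's logic under its stated model of the data,
not robustness to annotation noise in real corpora.

## Problem sizes

The test suite and the acceptance script run at desk scale, chosen to
exercise every code path with comfortable statistical resolution: default
synthetic corpora of 150 genomes (~1,200 loci, ~550 PULs), recovery runs
of 30-40 genomes over 10 seeds, exhaustive string-alignment oracle
checks over all pairs of length ≤ 4 on a 3-letter alphabet plus sampled
longer pairs, and 1,000-replicate coverage simulation for the Wilcoxon
interval (n = 50 per sample, nominal 95%).

## Known limitations

* Locus delimitation is order-based; corpora annotated with very
  different gene-calling density will shift what `max_gap = 2` means.
* The REJECTED class covers any susC/D locus without an adjacent
  same-strand pair, including lone-gene fragments that other curations
  might discard before counting.
* Copy-aware clustering (Ruzicka distances) has no exact-equality
  interpretation at threshold 0 beyond copy-aware uniqueness itself.
* Synteny scoring treats all retained genes as equally weighted symbols;
  it does not model gene length, orientation within the locus, or
  intergenic distance.
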