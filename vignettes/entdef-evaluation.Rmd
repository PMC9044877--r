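---
title: "Building and evaluating enhancer-to-target-gene definitions"
author: "entforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating enhancer-to-target-gene definitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Most genomic-region analyses assign a distal regulatory element (an
enhancer, silencer or insulator more than a few kilobases from any
transcription start site) to the gene with the nearest TSS.  Because
enhancers act over long ranges through chromosomal contact, the nearest
gene is often the wrong gene, and downstream gene-set enrichment (GSE)
results inherit the error.  entforge builds *enhancer-to-target-gene
definitions* (EnTDefs): genome-wide maps from distal loci to the gene or
genes they are inferred to regulate, assembled from combinations of
enhancer-region evidence and enhancer-gene link evidence, and provides the
machinery to decide *which* combination works best.

## The definition-assembly model

An EnTDef is assembled as a fixed pipeline:

1. **Enhancer regions.**  The selected enhancer sources (any non-empty
   subset) are unioned and merged at the base level.  Merged enhancers
   inherit the label of every source that overlaps them, because the
   evidence streams are unioned before linking and per-fragment provenance
   is otherwise lost.
2. **Promoter trimming.**  Every base within the promoter window
   `[tss - w, tss + w)` (default `w` = 5 kb) of any TSS is subtracted, so
   definitions describe distal space only.  This invariant is asserted in
   the test suite by literal interval intersection.
3. **Optional extension.**  Enhancers shorter than 1 kb are replaced by a
   1-kb window centred on their midpoint.  "Extension to 1 kb" is read as
   a floor: longer enhancers pass through unchanged.  Extension can invade
   a promoter window, so trimming is re-applied afterwards; link overlap
   is computed on the post-extension fragments.
4. **Linking.**  Three kinds of link evidence are supported:
   *pair tables* (precomputed enhancer-interval-to-gene links, e.g.
   correlation-derived), *paired anchors* (BEDPE interactions: one anchor
   must overlap an enhancer by at least 1 bp, the other a promoter
   window; both orientations are tried), and *loops* (an interval is a
   loop span; if the span contains the TSSs of at most `k` genes, every
   enhancer overlapping the span links to all of them, with `k` = 1, 2, 3
   as the L1/L2/L3 variants).  Loop gene membership is decided by TSS
   position, not gene-body containment, because the TSS is the regulatory
   anchor used everywhere else in the pipeline.  Links from all selected
   evidence are unioned; enhancers that end up with no link are dropped
   (a record must map a locus to a gene).
5. **Optional nearest-TSS fallback** (`nearest_all`).  The complement of
   (promoter windows plus assembled loci) is partitioned by nearest TSS
   and appended as fallback records, giving 100% coverage of distal space.

Crossing `s` enhancer sources, `k` non-loop link methods, `v` loop
variants and the two binary toggles gives
`(2^s - 1) * ((2^k - 1)(1 + v) + v) * 4` configurations; for the
canonical 4/3/3 case that is 15 x 31 x 2 x 2 = 1860, with 465 core
configurations when both toggles are off.  A cell-type-restricted mode
limits the link combinations to the interaction track and/or one loop
variant (`1 + 2v` = 7 combinations, hence 420 configurations), since
correlation-derived pair tables are aggregates over many cell types.

### Coordinate conventions and tie-breaking

All coordinates are 0-based, half-open (BED convention), including the
gene-registry TSV.  The TSS is a single explicitly supplied base offset --
it is input data, never recomputed from the gene body, because strand
arithmetic is the classic source of off-by-one bugs.  Touching intervals
merge (coverage semantics).  In the nearest-TSS partition, the boundary
between adjacent TSSs `t1 < t2` sits at `ceiling((t1 + t2) / 2)`: the
left gene receives all strictly-lower bases and an exactly equidistant
base belongs to the downstream gene.  Because the partition is a set of
half-open intervals, peak-midpoint assignment on a boundary is resolved
structurally and needs no secondary tie-break rule.

## Peak assignment and the enrichment model

A peak is represented by its midpoint `floor((start + end) / 2)` and
increments the count of every gene holding a record that contains the
midpoint (an enhancer can be assigned to multiple genes; a 1-bp-overlap
rule is available via `overlap_rule = "any"`).  For a peak set and a
definition this yields per-gene counts `y_g` and locus lengths `L_g`.

The count-based GSE model is a negative-binomial regression

    log mu_g = b0 + b1 * member_g + f(log10 L_g),    y_g ~ NB(mu_g, theta)

where `member_g` indicates gene-set membership and `f` is by default a
natural cubic spline with 5 degrees of freedom (falling back to a linear
term, then to no adjustment, when the profile has too few distinct
lengths).  The length adjustment matters: longer loci catch more peaks
for purely geometric reasons.  Two tests of `b1 = 0` are provided:

* `nb_score` -- the one-degree score test computed from the *null* fit
  only (working weights and a QR projection of the membership vector),
  making a full scan over thousands of terms cheap;
* `nb_lrt` -- the likelihood-ratio chi-square with one degree of freedom,
  refitting the full model per term at fixed dispersion.

`theta` is estimated once per peak set on the null (intercept + length)
model by maximum likelihood and reused across terms; per-term dispersion
would defeat the point of the score test, and a failure of the dispersion
fit falls back to Poisson with a warning.  Both tests report two-sided
p-values with the direction (enriched/depleted) carried separately.
Fisher's exact test on the has-peak-by-membership table and a one-sided
binomial test (observed in-set peak count against the in-set share of
locus length, the GREAT-style geometry) are included as baselines; the
binomial variant counts a peak at most once per term even when multi-gene
loci repeat it across genes.  FDR control is Benjamini-Hochberg
throughout.

On simulated null profiles (length-dependent counts, no membership
effect) both NB tests hold their size -- the acceptance suite requires
empirical type-I error within [0.03, 0.07] at alpha = 0.05 over 2000
replicates -- and their p-values are rank-correlated above 0.95, the
score test being the slightly conservative one.

## Evaluating definitions against TF annotations

The evaluation assumes that a transcription factor tends to regulate
genes in the biological processes it is annotated to, so a better
definition should make the TF's annotated terms rise in a GSE of the TF's
distal binding peaks.  For each TF:

* **Positives** are the most specific annotated terms (leaves of the
  assigned set in the ontology DAG) plus all their ancestors
  (`standard` scheme), or leaves plus parents and grandparents only after
  removing electronically-inferred annotations
  (`conservative_no_iea` scheme).  Terms are size-filtered to 15-2000
  genes; the same filter is applied to the negative pool.
* **Negatives** are drawn one per positive from terms outside the
  positives' DAG neighbourhood (standard: their offspring and siblings;
  conservative: their ancestors, those ancestors' siblings, and their
  offspring), matched on term size using fixed half-open bins of 20 genes
  (nearest non-empty bin as fallback), without replacement within a
  repetition.  Sampling is repeated 10 times by default with fresh draws,
  seeded by (seed, TF, repetition).
* A term is **called** when its FDR is below 0.05 *and* its direction is
  enriched; depleted terms are never called.  TP/FP/TN/FN over positives
  and negatives give precision, recall and `F1 = 2PR/(P+R)` (defined 0
  when nothing is called).

F1 is averaged over repetitions, then over a TF's peak sets, then over
TFs -- so a TF assayed by many datasets does not dominate the ranking
(the averaging order is a package choice; the alternative would weight
TFs by dataset count).  Definitions are ranked by mean F1, the top set is
cut where a paired per-TF Wilcoxon signed-rank test against rank 1 first
drops below p = 0.01, and each definition is compared to the distal
nearest-gene baseline with BH control.  A per-feature contribution
analysis pairs configurations differing by exactly one feature and
reports the share of pairs where the with-feature member is significantly
better.

The signed-rank test is implemented with the Pratt treatment of zero
differences, mid-ranks for ties, and an exact sign-convolution null for
up to 25 non-zero pairs (tie-robust normal approximation beyond); the
exact branch is verified against full 2^n sign enumeration in the tests.
The paper-style ROC/PR sweep over p-value cutoffs uses trapezoidal AUROC
and step-interpolated AUPRC (linear interpolation in PR space is
incorrect), and the regulome-vs-expression concordance AUC repeats
size-matched sampling of insignificant terms (p > 0.5) against the top
significant expression terms (q < 0.05), reporting the mean AUROC over
samplings.

## Pair benchmarks and the interceding-gene analysis

A labeled benchmark pair (enhancer interval, gene, positive/negative) is
predicted positive when some definition record overlaps the enhancer by
at least 1 bp *and* carries the same gene; the four-way confusion counts
give sensitivity, specificity, precision and `F1 = 2TP/(2TP+FP+FN)`.
Negative subsampling to a 1:4 ratio never touches positives, so
sensitivity is invariant to it while precision is not.  Dataset-level
similarity uses the overlap coefficient: matched pairs of the smaller set
divided by the smaller set's size.  Before any comparison, pair datasets
are preprocessed by promoter trimming and enhancer merging, with gene
links carried through to the merged intervals.

The interceding-gene analysis asks which functions are systematically
mis-served by nearest-gene assignment: for every non-fallback link the
query span runs from the enhancer's outermost coordinate to the target
body's outermost coordinate, and the count is the number of other genes
whose body overlaps the span.  Per-gene means are transformed by the
rank-based inverse normal transform (Blom offset 3/8 -- the offset of the
reference implementation the field uses), and each term is tested by
logistic regression of membership on the INT score.  The reported
statistic is the negated slope, so positive values mean "enriched among
genes with few interceding genes"; complete separation triggers a
Firth-penalized refit, flagged in the output.  The published round-trip
of exponentiating the scores and log-transforming them inside the
regression cancels exactly, so the regression runs directly on INT
scores.  Across definitions, per-term p-values are combined by the plain
(unweighted) harmonic mean, BH-adjusted, and redundant terms are removed:
within each direction, a significant term is dropped when a parent, child
or sibling ranks above it.

## The synthetic regulome

All tests run on generated data; nothing is downloaded.  The generator
emulates the *statistical* structure the evaluation relies on and nothing
else:

* one 10-Mb chromosome with 300 genes (TSSs on a jittered grid with 3-kb
  minimum spacing, bodies 2-100 kb, explicit strands and TSSs);
* a 120-term ontology with a layered DAG of depth 4; term sizes are
  log-uniform between 10 and 400 genes but capped at a third of the gene
  universe -- GO-scale term sizes assume a ~20k-gene genome, and without
  the cap a TF's annotated terms can union to the whole toy universe,
  destroying the very contrast the evaluation measures;
* a pool of disjoint distal enhancers (400 per source, 200-2000 bp),
  each appearing in at least one of 3 partially overlapping sources;
* a ground-truth link map in which half the enhancers belong to one of 3
  synthetic TFs and target genes of that TF's 3-8 annotated terms;
  pair-table, paired-anchor and loop evidence are derived from the truth,
  with spurious links added at rate 0.05 and true links dropped at rate
  0.10 (loop evidence is emitted only where the loop span implies no link
  beyond the truth, so a zero-noise assembly reproduces the truth
  exactly);
* TF peak sets of 2000 peaks, 100-500 bp wide; with probability 0.6 a
  peak falls uniformly inside an enhancer linked to a gene of the TF's
  terms, otherwise uniformly in the genome.

What passing tests show: the pipeline recovers a planted
enhancer-to-gene correspondence and ranks it above a link-shuffled decoy
with identical marginals in at least 95% of seeded runs, and the
statistics are calibrated on data satisfying the model assumptions.  What
they do not show: robustness to real-chromatin structure (TADs, CTCF
orientation, cell-type specificity of enhancers), assay-specific error,
or annotation-quality effects -- none of which the generator models.

## Problem sizes and numerical choices

The shipped suites use deliberately small instances: per-base oracle
equivalence on chromosomes up to 10 kb over 1000 randomized cases;
statistical calibration on 2000 null profiles of 200 genes with
theta = 5; ground-truth recovery over 20 seeds at the generator defaults
above.  These sizes make every expected value either closed-form or
recomputable by a brute-force oracle inside the test run itself.  Other
numerical choices: p-values are clamped to (0, 1]; the spline basis
degrades gracefully on degenerate length profiles; score-test terms whose
membership vector is collinear with the null design are skipped and
reported; ranking ties are broken by definition name for determinism.

## Known limitations

* The NB enrichment model is this package's own specification of a
  count-with-length-offset regression; it is not a re-implementation of
  any particular published tool's internals, and coefficients are not
  numerically comparable to them.
* Per-peak weights enter as linearly accumulated counts (rounded for the
  NB family); this is the minimal reading of weighted enrichment and is
  flagged as such.
* The binomial baseline's handling of multi-gene loci (one count per
  term) is one of several defensible conventions; it is documented, not
  canonical.
* Cell-type-restricted mode changes only the enumeration of link
  combinations; the package does not model cell-type identity of the
  evidence itself.
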