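---
title: "Predicting gene function by blending expression embeddings, homology transfer and annotation priors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting gene function by blending expression embeddings, homology transfer and annotation priors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goblend)
```

# The problem

Most genes in sequenced genomes lack experimentally determined Gene
Ontology (GO) annotations, and for non-coding genes protein-based
annotation tools do not apply at all. The guilt-by-association principle
— genes with similar expression profiles, or with homologous sequences,
tend to share function — supports transfer of annotations from
characterized genes to queries. `goblend` implements a four-channel
predictor built on that principle and a CAFA-style evaluation stack for
it. Each channel emits per-term confidences in [0, 1]; a logistic
combiner fuses them; a hierarchical post-processing step makes the final
scores consistent with the GO DAG.

# The expression channel (EPGP)

## Normalization

The training expression matrix $E = (e_{ij})_{m \times l}$ (genes by
samples) is z-scored per sample column and reduced by PCA to $h < l$
components. Sample panels are highly redundant — many experiments vary
together for reasons unrelated to function — and raw Euclidean distance
in the original space is dominated by whichever columns happen to have
the largest variance. Z-scoring equalizes column scales; PCA concentrates
the correlated (mostly biological) structure into few components.

Choices here:

* **$h$ default**: the smallest $h$ reaching 95 % cumulative explained
  variance, capped at $\min(m-1, l)$. Any fixed $h$ can be passed
  instead.
* **Zero-variance columns**: the standard deviation is replaced by 1
  (with a warning), so the column becomes all-zero after centring rather
  than producing divisions by zero or dropped samples.

## Embedding network and losses

A fully connected ReLU block maps the $h$-dimensional profile to an
embedding; the default widths are $1024{-}1024$ (the package's tests and
examples use $64{-}32$, which is ample at benchmark scale). The
embedding is L2-normalized, so the squared Euclidean distance divided by
4 lies in $[0,1]$, attaining 1 exactly at antipodal embeddings — a
convenient normalized dissimilarity.

Training combines two losses:

* **Batch-hard triplet loss.** Per anchor gene, the farthest positive
  and the nearest negative in the batch form the triplet
  $\max(d_{pos}^{max} + margin - d_{neg}^{min},\, 0)$, averaged over
  anchors that have both a positive and a negative. Two genes are
  positives when the F1 overlap of their ancestor-closed GO term sets
  exceeds the cutoff $c_f$ strictly.
* **Cross-entropy.** A sigmoid output layer attached to the embedding
  block predicts the gene-term annotation matrix; its mean binary
  cross-entropy, weighted by $\alpha$, is added. Pure metric learning
  can collapse fine-grained term information; the classification branch
  anchors the representation to the actual label structure.

Defaults: $margin = 0.2$, $\alpha = 1$, $c_f = 0.5$, Adam at learning
rate $10^{-3}$. These are conventional values for unit-sphere triplet
training; all are exposed in `tnp_config()`. Batches are stratified — 8
annotation classes by 4 genes, resampling with replacement inside small
classes — because uniform sampling of small multi-class panels often
yields batches with no valid triplet. One integer seed drives
initialization and batch sampling; identical inputs and seed reproduce
the weights bitwise. The analytic gradients (through the batch-hard
mining, the L2 normalization and the ReLU stack) are verified against
finite differences in the test suite.

## Prediction

For a query profile the pipeline applies the stored normalizer, embeds,
and blends two branches:

* **Rank transfer** $s_t$: the $K$ nearest training genes by normalized
  embedding distance act as templates; rank $r_i$ gets weight
  $w_i = 1 - (r_i - 1)/K$ and each term is scored by its
  weight-normalized frequency among templates. Default $K = 100$,
  capped at the training-set size.
* **Sigmoid branch** $s_c$: the output layer applied to the query.

The blend is $s = w\, s_t + (1 - w)\, s_c$ with $w = 0.5$ by default.
The rank-transfer rule mirrors the rank weighting of the WFS diagnostic
(below); it is deliberately isolated behind `rank_score()` so an
alternative neighbour-scoring rule can be swapped in without touching
training.

# Alignment channels and the prior

**GSAGP / PSAGP** score term $Q$ as
$\sum_k b_k I_k(Q) / \sum_k b_k$ over alignment templates, where $b_k$
is the BLAST bit-score and $I_k(Q)$ indicates the template's annotation.
Hits are filtered by e-value $\le 0.1$ and by a homology-contamination
rule: identity *strictly above* the cutoff (t1 = 60 % for nucleotide,
t2 = 30 % for protein alignments) is excluded, so a template exactly at
the cutoff is retained. Self-hits are always removed, and when a subject
contributes several HSPs only its best bit-score is kept — templates are
genes, not alignments. Protein subjects are mapped back to genes through
an id table; a query without a coding protein has no protein channel at
all (`NULL`, distinct from an empty hit list).

**NGP** scores every term by its frequency $N(Q)/N_{GO}$ among annotated
genes of the aspect — a query-independent prior that supplies sensible
confidences for shallow terms when the informative channels are silent.

# Hierarchy

GO annotation is hierarchical: a gene annotated with a term is implicitly
annotated with all its ancestors. Truth sets are therefore stored
ancestor-closed, and every emitted score vector is post-processed so a
term's score is the maximum over its descendants (itself included) —
parent scores never fall below child scores. The operation is idempotent
and never decreases a score; it is applied to each channel's output and
again after combination. Both `is_a` and `part_of` OBO relations count
as hierarchy edges by default (the common convention for GO propagation);
the whitelist is configurable. Cross-aspect edges are ignored and each
aspect is processed independently. Obsolete OBO terms are dropped with a
warning. The F1 functional similarity used for triplet pairing operates
on ancestor-closed sets by default, consistent with the closed truth
sets; `functional_similarity(closed = FALSE)` compares raw sets.

# Combiner

The consensus is a single fully connected layer with sigmoid output —
a logistic model over the (up to four) channel confidences of one
(gene, term) pair. One combiner is shared across all terms of an aspect:
per-term combiners would have almost no training signal for rare terms.
It is trained on the *validation* split (never on the channels' own
training genes, avoiding leakage) by full-batch gradient descent, 2000
iterations at rate 0.1, from a zero start (output 0.5 everywhere).
Non-coding genes lack the protein channel; rather than imputing it,
they route to a combiner trained without that input (the
expression + gene-alignment + prior subset). `select_subset()` accepts
the single-letter shorthand for any channel subset.

# Evaluation

* **Fmax**: precision and recall are pooled (micro) counts over all
  evaluated genes at each threshold, as is standard when a single
  summary per aspect is wanted; the threshold grid is every distinct
  score plus {0, 1}, so the maximization is exact. Genes predicting
  nothing at a threshold stay out of precision's denominator while their
  missed terms still count as false negatives.
* **AUPRC** flattens (gene, term) pairs — for each gene the union of its
  scored and true terms, unscored true terms entering at confidence 0 —
  and integrates the precision-recall curve with step interpolation.
* **Weighted averages** across species use gene counts as weights.
* **WFS / AVG_WFS**: for a query's $K$ ranked expression neighbours with
  functional similarities $FS_i$, $WFS = \sum w_i FS_i / \sum w_i$ with
  $w_i = 1 - (r_i-1)/K$, averaged over test genes — a direct diagnostic
  of how well an expression-similarity measure tracks functional
  similarity.
* **Term-centric AUROC** is the Mann-Whitney rank statistic with
  average-rank tie correction.

# The synthetic benchmark

The generator (`benchmark_spec()`, `simulate_benchmark()`,
`write_benchmark()`) builds everything the pipeline consumes:

* a random single-rooted DAG per aspect (each non-root term takes 1–2
  parents from strictly shallower levels, acyclic by construction), one
  distinct deepest leaf per function class;
* class-structured expression: centroids drawn on an $l$-sphere of
  radius `centroid_separation` (default 10 noise-sd units) plus
  isotropic Gaussian noise, split 85 / 5 / 10 into train / validation /
  test;
* optionally, `n_nuisance` sample columns with high-variance
  class-independent noise (default off). These emulate experiments whose
  variation is unrelated to function. They matter for one comparison:
  on clean isotropic clusters, raw-space Euclidean distance is already
  near-optimal and embedding cannot beat it; with nuisance columns the
  raw-space baseline degrades while the z-score + PCA + triplet front
  end suppresses them — which is precisely the failure mode of raw
  distance on real panels that motivates feature-space mapping. The
  clustered benchmarks in the acceptance tests therefore set
  `n_nuisance = 10` of 40 columns at sd 8;
* sequence families: one random DNA template per class, members
  point-mutated to the identities of `identity_grid`
  (default 95/70/55/25 %), proteins derived by a fixed arbitrary 3-mer
  translation so gene- and protein-level identities stay correlated
  (mimicking the empirical ~2:1 relation between nucleotide and protein
  identity cutoffs without fitting it), a fraction of genes left
  non-coding; alignment hit tables in outfmt-6 layout computed from
  columnwise identity with pseudo bit-score `2 * matches`, within-class
  pairs only.

All randomness flows from one seed. What the generator does **not**
emulate: realistic microarray noise, batch effects, codon usage,
alignment statistics (e-values are pseudo-values), incomplete or noisy
annotations, and the extreme class imbalance of real GO corpora. Passing
tests on this benchmark show the machinery is correct and that the
design behaves as intended under its assumptions — not that real-data
accuracy figures would be reproduced.

# Problem sizes and numerical choices

Tests and examples run 2–4 classes × 15–30 genes × 20–40 samples with
64–32-unit layers, 12–30 epochs and $K = 10$ — sizes chosen so the whole
suite executes in well under a minute while every phenomenon of interest
(margin structure, channel complementarity, routing, hierarchy) is
exercised; the 1024-unit / $K = 100$ defaults remain for realistic
panels. Other numerical details: cross-entropy scores are clipped to
$[10^{-7}, 1-10^{-7}]$; an all-zero pre-normalization embedding gets an
epsilon before L2 normalization (with a warning); `pairwise_distance()`
rejects inputs whose norm deviates from 1 by more than $10^{-3}$; a
batch with no valid anchor contributes zero loss with a warning rather
than an error, since stratified sampling makes it rare.

# Known limitations

* Expression models are per species and per aspect; cross-species
  normalization is out of scope.
* The homology channels consume precomputed tabular alignments; the
  package does not invoke an aligner.
* The combiner is intentionally shallow (four weights and a bias);
  stacking or per-term calibration is future work.
* Pooled precision/recall is the only implemented Fmax variant;
  per-gene-averaged CAFA precision would require genes with empty
  predictions to be handled differently.
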