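# goblend

Gene Ontology (GO) term prediction for protein-coding and non-coding genes
by blending four complementary evidence channels:

1. **EPGP** — expression-profile prediction through a triplet-network
   embedding: gene expression profiles are z-scored, reduced by PCA, and
   mapped by a ReLU network into a space where distance tracks *functional*
   similarity, trained with a batch-hard triplet loss plus a multi-label
   cross-entropy branch.
2. **GSAGP** — gene-level alignment transfer: GO terms of nucleotide
   alignment templates, weighted by bit-score.
3. **PSAGP** — protein-level alignment transfer through a protein-to-gene
   id map (absent for non-coding queries).
4. **NGP** — a naive prior: each term's frequency among annotated genes.

Per-term confidences from the four channels are fused by a one-layer
logistic combiner (non-coding genes route to a combiner trained without
the protein channel) and made hierarchically consistent over the GO DAG.
Evaluation follows the CAFA conventions: Fmax, AUPRC, term-centric AUROC,
and the rank-weighted functional-similarity diagnostic WFS/AVG_WFS.

## The model in brief

For genes \(i, j\) with unit-normalized embeddings \(u_i, u_j\), the
dissimilarity is the normalized squared Euclidean distance
\(d(i,j) = \lVert u_i - u_j \rVert^2 / 4 \in [0, 1]\). Training minimizes

    L = mean_i max( d_i,pos^max + margin − d_i,neg^min , 0 )  +  α · CE(S, Y)

where the hardest in-batch positive/negative per anchor define the triplet
term ("batch on hard"), two genes are positives when the F1 overlap of
their ancestor-closed GO sets exceeds a cutoff `cf`, and `CE` is the mean
binary cross-entropy of the sigmoid output branch against the gene-term
annotation matrix. Prediction blends a rank-weighted nearest-neighbour
transfer in embedding space (weights \(w_i = 1-(r_i-1)/K\)) with the
sigmoid branch: \(s = w\,s_t + (1-w)\,s_c\).

Alignment channels score
\(S(Q) = \sum_k b_k I_k(Q) / \sum_k b_k\) over templates surviving an
e-value cutoff (0.1) and a homology-contamination cutoff (identity
strictly above t1 = 60 % for genes, t2 = 30 % for proteins, is excluded).
The prior scores \(S(Q) = N(Q)/N_{GO}\). All score sets are
post-processed so that every term scores at least as high as each of its
children.

## Worked example

Everything runs on a self-contained synthetic benchmark — no downloads.

```r
library(goblend)

spec  <- benchmark_spec(n_classes = 3, genes_per_class = 30,
                        n_nuisance = 10, seed = 71)
bench <- simulate_benchmark(spec)
res   <- run_pipeline(bench, "MF",
                      tnp = tnp_config(layers = c(64, 32), epochs = 30,
                                       K = 10, seed = 71))
evaluate_predictions(res$combined, res$truth)
```

Printed output of this exact run:

```
consensus: Fmax 1.000 at t = 0.95, AUPRC 1.000 (10 test genes)
EPGP   Fmax 1.000  AUPRC 1.000
GSAGP  Fmax 1.000  AUPRC 1.000
PSAGP  Fmax 0.952  AUPRC 0.947
NGP    Fmax 0.584  AUPRC 0.608
```

The benchmark has three expression classes, each tied to one leaf of a
random 16-term molecular-function DAG; ten of the forty expression samples
carry high-variance class-independent noise. The consensus recovers the
held-out annotations perfectly (Fmax 1.0: at the best threshold every
predicted term of every test gene is correct and complete). Individually,
the expression and gene-alignment channels are near-perfect here, the
protein channel loses a little to non-coding genes and the coarser protein
identity, and the frequency prior — identical for every query — tops out
at Fmax 0.58, the score of always predicting the common shallow terms.
The per-gene score vectors (`res$combined`) are parent-monotone
confidences in [0, 1].

The same pipeline is scriptable from a shell:

```sh
Rscript exec/goblend simulate --out bench --seed 3
Rscript exec/goblend run --dir bench --aspect MF --seed 3 --out preds.tsv
Rscript exec/goblend evaluate --predictions preds.tsv --dir bench --aspect MF
```

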