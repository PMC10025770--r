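# Self-contained synthetic benchmark with the statistical structure the
# predictor assumes: class-structured expression profiles, a random
# single-rooted GO DAG per aspect with class-linked leaf annotations, and
# mutated sequence families yielding alignment hit tables — so training,
# prediction, combination and evaluation all run without external data.

#' Specify a synthetic benchmark
#'
#' @param n_classes Number of function classes (default 4).
#' @param genes_per_class Genes per class (default 30).
#' @param n_samples Expression samples l (default 40).
#' @param noise_sd Within-class Gaussian expression noise sd (default 1).
#' @param centroid_separation Radius of the sphere the class centroids are
#'   drawn on, in noise-sd units of the raw space (default 10: clearly
#'   separated classes, non-trivial overlap after projection).
#' @param n_nuisance Number of sample columns carrying additional
#'   high-variance, class-independent noise (default 0).  These emulate
#'   experiments whose variation is unrelated to function — the kind of
#'   redundancy that corrupts raw-space distances and that the z-score +
#'   PCA + metric-learning front end is designed to suppress.
#' @param nuisance_sd Standard deviation of the nuisance noise (default 8).
#' @param dag_terms_per_aspect GO terms per aspect DAG (default 15).
#' @param term_depth Depth of the DAG below the root (default 3).
#' @param extra_leaf_prob Probability that a gene carries one extra random
#'   leaf annotation beyond its class leaf (default 0).
#' @param fraction_noncoding Fraction of genes without a coding protein
#'   (default 0.1).
#' @param sequence_length Gene sequence length in nucleotides, a multiple
#'   of 3 (default 120).
#' @param identity_grid Percent identities (to the class template) that the
#'   mutated class members cycle through (default `c(95, 70, 55, 25)`).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_classes = 4, genes_per_class = 30,
                           n_samples = 40, noise_sd = 1,
                           centroid_separation = 10,
                           n_nuisance = 0, nuisance_sd = 8,
                           dag_terms_per_aspect = 15, term_depth = 3,
                           extra_leaf_prob = 0, fraction_noncoding = 0.1,
                           sequence_length = 120,
                           identity_grid = c(95, 70, 55, 25), seed = 1L) {
  stopifnot(n_classes >= 1, genes_per_class >= 1, n_samples >= 1,
            noise_sd > 0, centroid_separation >= 0,
            n_nuisance >= 0, n_nuisance <= n_samples, nuisance_sd > 0,
            dag_terms_per_aspect >= term_depth, term_depth >= 1,
            extra_leaf_prob >= 0, extra_leaf_prob <= 1,
            fraction_noncoding >= 0, fraction_noncoding < 1,
            sequence_length >= 50, sequence_length %% 3 == 0,
            all(identity_grid > 0), all(identity_grid <= 100))
  structure(list(n_classes = as.integer(n_classes),
                 genes_per_class = as.integer(genes_per_class),
                 n_samples = as.integer(n_samples), noise_sd = noise_sd,
                 centroid_separation = centroid_separation,
                 n_nuisance = as.integer(n_nuisance),
                 nuisance_sd = nuisance_sd,
                 dag_terms_per_aspect = as.integer(dag_terms_per_aspect),
                 term_depth = as.integer(term_depth),
                 extra_leaf_prob = extra_leaf_prob,
                 fraction_noncoding = fraction_noncoding,
                 sequence_length = as.integer(sequence_length),
                 identity_grid = identity_grid, seed = as.integer(seed)),
            class = "benchmark_spec")
}

#' Generate a random GO DAG with class-linked leaves
#'
#' Builds one single-rooted random DAG per aspect: terms are laid out in
#' levels 1..`term_depth` under the root and each non-root term draws 1-2
#' parents from strictly shallower levels (acyclic by construction).  Each
#' function class is assigned a distinct deepest-level leaf per aspect;
#' gene annotation sets are the ancestor closures of those leaves.
#'
#' @param spec A [benchmark_spec()].
#' @param aspects Aspects to generate (default all three).
#' @return List with `dag` (a [go_dag]) and `class_leaves` (list: aspect ->
#'   character vector of one leaf term per class).
#' @export
make_godag <- function(spec, aspects = c("MF", "BP", "CC")) {
  set.seed(spec$seed)
  n <- spec$dag_terms_per_aspect
  depth <- spec$term_depth
  terms <- character(0); parents <- list(); aspect <- character(0)
  class_leaves <- list()
  counter <- 0L
  for (a in aspects) {
    ids <- sprintf("GO:%07d", counter + seq_len(n + 1L))
    counter <- counter + n + 1L
    root <- ids[[1L]]
    rest <- ids[-1L]
    # at least one term per level, at least n_classes on the deepest
    lvl <- integer(0)
    need_deep <- min(spec$n_classes, max(1L, length(rest) - depth + 1L))
    fixed <- c(seq_len(depth - 1L), rep(depth, need_deep))
    if (length(fixed) > length(rest))
      stop("dag_terms_per_aspect too small for term_depth and n_classes")
    lvl <- c(fixed, sample(depth, length(rest) - length(fixed),
                           replace = TRUE))
    lvl <- sort(lvl)
    level_of <- stats::setNames(c(0L, lvl), c(root, rest))
    for (tm in rest) {
      shallower <- names(level_of)[level_of < level_of[[tm]]]
      k <- min(length(shallower), sample(1:2, 1L))
      parents[[tm]] <- sample(shallower, k)
    }
    parents[[root]] <- character(0)
    terms <- c(terms, ids)
    aspect <- c(aspect, stats::setNames(rep(a, n + 1L), ids))
    deepest <- rest[lvl == depth]
    # distinct leaf per class; recycle only if classes outnumber leaves
    class_leaves[[a]] <- deepest[1L + (seq_len(spec$n_classes) - 1L) %%
                                   length(deepest)]
  }
  list(dag = go_dag(terms, parents, aspect), class_leaves = class_leaves)
}

#' Generate class-structured expression data and annotations
#'
#' Class centroids are drawn uniformly on an l-sphere of radius
#' `centroid_separation`; each gene's profile is its class centroid plus
#' isotropic Gaussian noise, and the last `n_nuisance` sample columns (if
#' any) receive additional class-independent high-variance noise.  Genes are split 85% / 5% / 10% into
#' training / validation / test sets.  Annotations tie each gene to its
#' class leaf in every aspect (ancestor closure applied downstream by
#' [annotation_db()]).
#'
#' @param spec A [benchmark_spec()].
#' @param godag Result of [make_godag()].
#' @return List with `expr` ([expression_matrix]), `annotations`
#'   (data.frame gene_id/go_id/aspect of leaf-level assignments), `classes`
#'   (named integer class of each gene) and `splits` (list train/val/test
#'   of gene ids).
#' @export
make_expression <- function(spec, godag) {
  set.seed(spec$seed + 1L)
  m <- spec$n_classes * spec$genes_per_class
  l <- spec$n_samples
  genes <- sprintf("g%04d", seq_len(m))
  classes <- stats::setNames(rep(seq_len(spec$n_classes),
                                 each = spec$genes_per_class), genes)
  centroids <- matrix(stats::rnorm(spec$n_classes * l), spec$n_classes)
  centroids <- centroids / sqrt(rowSums(centroids^2)) *
    spec$centroid_separation
  values <- centroids[classes, , drop = FALSE] +
    matrix(stats::rnorm(m * l, sd = spec$noise_sd), m, l)
  if (spec$n_nuisance > 0L) {
    cols <- seq.int(l - spec$n_nuisance + 1L, l)
    values[, cols] <- values[, cols] +
      matrix(stats::rnorm(m * spec$n_nuisance, sd = spec$nuisance_sd),
             m, spec$n_nuisance)
  }
  expr <- expression_matrix(values, genes, sprintf("s%03d", seq_len(l)))

  rows <- list()
  for (a in names(godag$class_leaves)) {
    leaves <- godag$class_leaves[[a]][classes]
    rows[[a]] <- data.frame(gene_id = genes, go_id = leaves,
                            aspect = a, stringsAsFactors = FALSE)
    if (spec$extra_leaf_prob > 0) {
      extra <- genes[stats::runif(m) < spec$extra_leaf_prob]
      if (length(extra))
        rows[[paste0(a, "_extra")]] <- data.frame(
          gene_id = extra,
          go_id = sample(godag$class_leaves[[a]], length(extra),
                         replace = TRUE),
          aspect = a, stringsAsFactors = FALSE)
    }
  }
  annotations <- do.call(rbind, rows)
  rownames(annotations) <- NULL

  perm <- sample(genes)
  n_train <- floor(0.85 * m); n_val <- floor(0.05 * m)
  splits <- list(train = sort(perm[seq_len(n_train)]),
                 val = sort(perm[n_train + seq_len(n_val)]),
                 test = sort(perm[-seq_len(n_train + n_val)]))
  list(expr = expr, annotations = annotations, classes = classes,
       splits = splits)
}

# fixed arbitrary codon-like translation: every nucleotide 3-mer maps
# deterministically to one of 20 letters, so gene-level identity and
# protein-level identity stay correlated
.translate3 <- function(seq) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
  codons <- substring(seq, seq(1L, nchar(seq) - 2L, 3L),
                      seq(3L, nchar(seq), 3L))
  base_val <- c(A = 0L, C = 1L, G = 2L, T = 3L)
  idx <- vapply(strsplit(codons, ""), function(b)
    sum(base_val[b] * c(16L, 4L, 1L)), 0L)
  paste(aa[idx %% 20L + 1L], collapse = "")
}

.mutate_to_identity <- function(seq, identity) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1L]]
  n_mut <- round(length(chars) * (1 - identity / 100))
  if (n_mut > 0L) {
    pos <- sample(length(chars), n_mut)
    for (p in pos)
      chars[[p]] <- sample(setdiff(bases, chars[[p]]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate sequence families and alignment hit tables
#'
#' Each class gets a random DNA template; the other members are point
#' mutated copies hitting the requested identities of `identity_grid`
#' (cycled through the class).  Coding genes get a protein via a fixed
#' 3-mer translation table; `fraction_noncoding` genes get none.  Hit
#' tables in BLAST outfmt-6 layout are computed from columnwise identity
#' with pseudo bit-score `2 * matches`, within-class pairs only (the pairs
#' a real aligner would report).
#'
#' @param spec A [benchmark_spec()].
#' @param classes Named integer vector: gene -> class (from
#'   [make_expression()]).
#' @return List with `gene_seqs`, `protein_seqs` (named character vectors),
#'   `id_map` (data.frame protein_id/gene_id), `gene_hits`, `protein_hits`
#'   (outfmt-6-style data.frames).
#' @export
make_sequences <- function(spec, classes) {
  set.seed(spec$seed + 2L)
  genes <- names(classes)
  bases <- c("A", "C", "G", "T")
  L <- spec$sequence_length
  gene_seqs <- stats::setNames(character(length(genes)), genes)
  for (k in seq_len(spec$n_classes)) {
    members <- genes[classes == k]
    template <- paste(sample(bases, L, replace = TRUE), collapse = "")
    gene_seqs[[members[[1L]]]] <- template
    others <- members[-1L]
    if (length(others)) {
      idents <- spec$identity_grid[1L + (seq_along(others) - 1L) %%
                                     length(spec$identity_grid)]
      for (i in seq_along(others))
        gene_seqs[[others[[i]]]] <- .mutate_to_identity(template,
                                                        idents[[i]])
    }
  }

  n_nc <- floor(spec$fraction_noncoding * length(genes))
  noncoding <- if (n_nc > 0L) sort(sample(genes, n_nc)) else character(0)
  coding <- setdiff(genes, noncoding)
  protein_seqs <- stats::setNames(
    vapply(gene_seqs[coding], .translate3, ""), paste0("P_", coding))
  id_map <- data.frame(protein_id = paste0("P_", coding), gene_id = coding,
                       stringsAsFactors = FALSE)

  hit_rows <- function(ids, seqs) {
    out <- list()
    for (k in seq_len(spec$n_classes)) {
      members <- ids[ids %in% names(seqs)]
      members <- members[classes[sub("^P_", "", members)] == k]
      for (q in members) for (s in members) {
        pid <- naive_pairwise_identity(seqs[[q]], seqs[[s]])
        matches <- round(pid / 100 * nchar(seqs[[q]]))
        out[[length(out) + 1L]] <- data.frame(
          qseqid = q, sseqid = s, pident = round(pid, 2),
          length = nchar(seqs[[q]]), mismatch = nchar(seqs[[q]]) - matches,
          gapopen = 0L, qstart = 1L, qend = nchar(seqs[[q]]),
          sstart = 1L, send = nchar(seqs[[q]]),
          evalue = 10^(-pmin(matches / 5, 180)), bitscore = 2 * matches,
          stringsAsFactors = FALSE)
      }
    }
    if (!length(out)) return(NULL)
    do.call(rbind, out)
  }
  list(gene_seqs = gene_seqs, protein_seqs = protein_seqs,
       id_map = id_map,
       gene_hits = hit_rows(genes, gene_seqs),
       protein_hits = hit_rows(paste0("P_", coding), protein_seqs))
}

#' Simulate a complete benchmark in memory
#'
#' Runs [make_godag()], [make_expression()] and [make_sequences()] under
#' one seed and assembles the pieces every module consumes.
#'
#' @param spec A [benchmark_spec()].
#' @return List with `spec`, `dag`, `class_leaves`, `expr`, `annotations`,
#'   `classes`, `splits`, `sequences` (the [make_sequences()] output) and
#'   `annots` (an [annotation_db] over all genes).
#' @export
simulate_benchmark <- function(spec = benchmark_spec()) {
  gd <- make_godag(spec)
  ex <- make_expression(spec, gd)
  sq <- make_sequences(spec, ex$classes)
  list(spec = spec, dag = gd$dag, class_leaves = gd$class_leaves,
       expr = ex$expr, annotations = ex$annotations, classes = ex$classes,
       splits = ex$splits, sequences = sq,
       annots = annotation_db(ex$annotations, gd$dag))
}

#' Write a benchmark to plain-text fixture files
#'
#' Emits the file set all readers consume: `expression.tsv`, `go.obo`
#' (minimal OBO dialect), `annotations.tsv`, `gene.fasta`,
#' `protein.fasta`, `gene_hits.tsv`, `protein_hits.tsv`, `idmap.tsv`,
#' `splits.json` and a `manifest.json` recording the spec.
#'
#' @param bench Result of [simulate_benchmark()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  expr_df <- data.frame(gene_id = rownames(bench$expr),
                        unclass(bench$expr), check.names = FALSE)
  utils::write.table(expr_df, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dag <- bench$dag
  ns_map <- c(MF = "molecular_function", BP = "biological_process",
              CC = "cellular_component")
  obo <- c("format-version: 1.2", "")
  for (tm in dag$terms) {
    obo <- c(obo, "[Term]", paste0("id: ", tm),
             paste0("name: synthetic term ", tm),
             paste0("namespace: ", ns_map[[dag$aspect[[tm]]]]),
             paste0("is_a: ", dag$parents[[tm]]), "")
  }
  writeLines(obo, p("go.obo"))

  utils::write.table(bench$annotations, p("annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  write_fasta <- function(seqs, path) {
    writeLines(unlist(lapply(names(seqs), function(id)
      c(paste0(">", id), seqs[[id]]))), path)
  }
  write_fasta(bench$sequences$gene_seqs, p("gene.fasta"))
  write_fasta(bench$sequences$protein_seqs, p("protein.fasta"))

  write_hits <- function(hits, path) {
    if (is.null(hits)) { file.create(path); return(invisible()) }
    utils::write.table(format(hits, scientific = TRUE, trim = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  write_hits(bench$sequences$gene_hits, p("gene_hits.tsv"))
  write_hits(bench$sequences$protein_hits, p("protein_hits.tsv"))
  utils::write.table(bench$sequences$id_map, p("idmap.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(bench$splits, p("splits.json"))
  jsonlite::write_json(unclass(bench$spec), p("manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
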