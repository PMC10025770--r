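# End-to-end orchestration: compute the four component score sets for a
# query, fuse them with the combiner, and enforce hierarchy — the complete
# train -> predict -> combine -> evaluate path on a benchmark.

.expand_scores <- function(scores, vocab) {
  out <- stats::setNames(numeric(length(vocab)), vocab)
  if (!is.null(scores) && length(scores)) {
    keep <- intersect(names(scores), vocab)
    out[keep] <- scores[keep]
  }
  out
}

#' Component GO scores for one query gene
#'
#' Computes the four per-term confidence maps for a query against a
#' training annotation database: expression embedding (EPGP), gene-level
#' alignment transfer (GSAGP), protein-level alignment transfer (PSAGP,
#' `NULL` for non-coding queries) and the frequency prior (NGP).  Each map
#' is expanded over the training vocabulary and made parent-monotone.
#'
#' @param gene Query gene id.
#' @param bench A benchmark list (see [simulate_benchmark()] /
#'   [load_benchmark()]).
#' @param aspect GO aspect.
#' @param model A trained [train_tnp()] model for the aspect.
#' @param annots_train [annotation_db] over the training genes only.
#' @param config A [homology_config()].
#' @return List of named score vectors `EPGP`, `GSAGP`, `PSAGP` (possibly
#'   `NULL`), `NGP`, all over the same training-term vocabulary.
#' @export
component_scores <- function(gene, bench, aspect, model, annots_train,
                             config = homology_config()) {
  vocab <- names(annots_train$term_count[[aspect]])
  train_genes <- names(annots_train$sets[[aspect]])
  pp <- function(s) postprocess_scores(.expand_scores(s, vocab), bench$dag)

  epgp <- predict_tnp(model, unclass(bench$expr)[gene, ])

  gh <- bench$sequences$gene_hits
  gh <- gh[gh$qseqid == gene & gh$sseqid %in% train_genes, , drop = FALSE]
  gh <- filter_homologs(gh, config$t1, config$evalue_cutoff, self = gene)
  gsagp <- alignment_transfer_score(gh, annots_train, aspect)

  id_map <- bench$sequences$id_map
  prot <- id_map$protein_id[match(gene, id_map$gene_id)]
  if (is.na(prot)) {
    psagp <- NULL
  } else {
    ph <- bench$sequences$protein_hits
    ph <- ph[ph$qseqid == prot &
               id_map$gene_id[match(ph$sseqid, id_map$protein_id)] %in%
                 train_genes, , drop = FALSE]
    ph <- filter_homologs(ph, config$t2, config$evalue_cutoff, self = prot)
    psagp <- psagp_score(ph, id_map, annots_train, aspect)
  }

  list(EPGP = pp(epgp), GSAGP = pp(gsagp),
       PSAGP = if (is.null(psagp)) NULL else pp(psagp),
       NGP = pp(ngp_score(annots_train, aspect)))
}

#' Homology-transfer configuration
#'
#' @param t1 Gene-level identity cutoff: templates more than `t1` percent
#'   identical to the query are excluded (default 60).
#' @param t2 Protein-level identity cutoff (default 30).
#' @param evalue_cutoff Maximum alignment e-value (default 0.1).
#' @return A list of class `homology_config`.
#' @export
homology_config <- function(t1 = 60, t2 = 30, evalue_cutoff = 0.1) {
  stopifnot(t1 > 0, t1 <= 100, t2 > 0, t2 <= 100, evalue_cutoff > 0)
  structure(list(t1 = t1, t2 = t2, evalue_cutoff = evalue_cutoff),
            class = "homology_config")
}

#' Run the full prediction pipeline on a benchmark
#'
#' Trains the expression model on the training split, assembles the four
#' component score sets for validation and test genes, fits the logistic
#' combiners on the validation split (the full four-method combiner for
#' coding genes and the three-method expression + gene-alignment + prior
#' combiner that non-coding genes route to), and returns hierarchy-
#' consistent consensus predictions for the test split along with the
#' per-method predictions and the held-out truth.
#'
#' @param bench A benchmark from [simulate_benchmark()] or
#'   [load_benchmark()].
#' @param aspect GO aspect to run.
#' @param tnp A [tnp_config()]; its seed governs the whole run.
#' @param homology A [homology_config()].
#' @param methods Method subset for coding genes (default the full set).
#' @return List with `combined` (named list gene -> confidence vector),
#'   `per_method` (method -> gene -> confidence vector), `truth` (gene ->
#'   term set), `combiners`, `model`, `annots_train`, `vocab`.
#' @export
run_pipeline <- function(bench, aspect = "MF", tnp = tnp_config(),
                         homology = homology_config(),
                         methods = c("EPGP", "GSAGP", "PSAGP", "NGP")) {
  methods <- select_subset(methods)
  ann <- bench$annotations
  annots_train <- annotation_db(
    ann[ann$gene_id %in% bench$splits$train, , drop = FALSE], bench$dag)
  truth_all <- annotation_db(ann, bench$dag)$sets[[aspect]]
  vocab <- names(annots_train$term_count[[aspect]])

  model <- train_tnp(bench$expr, annots_train, aspect, tnp)

  score_genes <- function(genes) {
    stats::setNames(lapply(genes, component_scores, bench = bench,
                           aspect = aspect, model = model,
                           annots_train = annots_train, config = homology),
                    genes)
  }
  val_scores <- score_genes(bench$splits$val)
  test_scores <- score_genes(bench$splits$test)

  # combiner training rows from the validation split
  make_rows <- function(scores, use_methods, coding_only) {
    x <- NULL; y <- integer(0)
    for (g in names(scores)) {
      sc <- scores[[g]]
      if (coding_only && is.null(sc$PSAGP)) next
      cols <- vapply(use_methods, function(m)
        if (is.null(sc[[m]])) numeric(length(vocab)) else sc[[m]][vocab],
        numeric(length(vocab)))
      x <- rbind(x, cols)
      y <- c(y, as.integer(vocab %in% truth_all[[g]]))
    }
    list(x = x, y = y)
  }

  combiners <- list()
  full <- make_rows(val_scores, methods, coding_only = "PSAGP" %in% methods)
  combiners$full <- train_combiner(full$x, full$y, methods,
                                   seed = tnp$seed)
  nc_methods <- setdiff(methods, "PSAGP")
  if ("PSAGP" %in% methods && length(nc_methods)) {
    nc <- make_rows(val_scores, nc_methods, coding_only = FALSE)
    combiners$noncoding <- train_combiner(nc$x, nc$y, nc_methods,
                                          seed = tnp$seed)
  }

  combine_gene <- function(sc) {
    cb <- if (is.null(sc$PSAGP) && !is.null(combiners$noncoding))
      combiners$noncoding else combiners$full
    x <- vapply(cb$methods, function(m)
      if (is.null(sc[[m]])) numeric(length(vocab)) else sc[[m]][vocab],
      numeric(length(vocab)))
    postprocess_scores(
      stats::setNames(combine_scores(cb, x), vocab), bench$dag)
  }
  combined <- lapply(test_scores, combine_gene)

  per_method <- stats::setNames(lapply(methods, function(m)
    lapply(test_scores, function(sc)
      if (is.null(sc[[m]])) stats::setNames(numeric(length(vocab)), vocab)
      else sc[[m]])), methods)

  list(combined = combined, per_method = per_method,
       truth = truth_all[bench$splits$test], combiners = combiners,
       model = model, annots_train = annots_train, vocab = vocab)
}

#' Load a benchmark from fixture files
#'
#' Reads the file set written by [write_benchmark()] back through the
#' package's format readers into the structure [run_pipeline()] consumes.
#'
#' @param dir Directory containing the benchmark files.
#' @return A benchmark list (without raw sequences; hit tables, expression,
#'   ontology, annotations, id map and splits are all restored).
#' @export
load_benchmark <- function(dir) {
  p <- function(f) file.path(dir, f)
  splits <- lapply(jsonlite::read_json(p("splits.json"),
                                       simplifyVector = TRUE),
                   as.character)
  dag <- read_obo(p("go.obo"))
  annotations <- read_annotation_tsv(p("annotations.tsv"))
  list(dag = dag, expr = read_expression(p("expression.tsv")),
       annotations = annotations,
       splits = splits,
       sequences = list(
         gene_hits = parse_blast_tabular(p("gene_hits.tsv")),
         protein_hits = parse_blast_tabular(p("protein_hits.tsv")),
         id_map = utils::read.delim(p("idmap.tsv"),
                                    stringsAsFactors = FALSE)),
       annots = annotation_db(annotations, dag))
}

#' Write predictions to TSV
#'
#' Flat per-(gene, term) table: `gene_id`, `go_id`, `aspect`, `method`,
#' `score`.
#'
#' @param predictions Named list gene -> named confidence vector.
#' @param path Output file.
#' @param aspect,method Constant columns recorded with every row.
#' @param min_score Rows below this confidence are omitted (default 0.01).
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, aspect, method = "EGPN",
                              min_score = 0.01) {
  rows <- do.call(rbind, lapply(names(predictions), function(g) {
    s <- predictions[[g]]
    s <- s[s >= min_score]
    if (!length(s)) return(NULL)
    data.frame(gene_id = g, go_id = names(s), aspect = aspect,
               method = method, score = round(unname(s), 6),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
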