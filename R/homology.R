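# Alignment-based GO transfer (gene- and protein-level) and the naive
# annotation-frequency prior.

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the standard 12-column tab-separated alignment format
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`) as written by `blastn`/`blastp -outfmt 6`, one hit per
#' line, input order preserved.
#'
#' @param path Path to a tabular hit file (no header).
#' @return A data.frame of hits; numeric fields are parsed, identifiers
#'   kept as character.  Zero rows for an empty file.
#' @export
parse_blast_tabular <- function(path) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(stats::setNames(
      data.frame(character(0), character(0), numeric(0), integer(0),
                 integer(0), integer(0), integer(0), integer(0),
                 integer(0), integer(0), numeric(0), numeric(0),
                 stringsAsFactors = FALSE), cols))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("line ", which(nf != 12L)[1L], ": expected 12 tab-separated ",
         "columns, found ", nf[nf != 12L][1L])
  m <- do.call(rbind, parts)
  df <- data.frame(qseqid = m[, 1L], sseqid = m[, 2L],
                   stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(m[, j]))
    if (anyNA(v))
      stop("line ", which(is.na(v))[1L], ": non-numeric value in column ",
           cols[j])
    df[[cols[j]]] <- if (j %in% 4:10) as.integer(v) else v
  }
  df
}

#' Filter alignment hits for annotation transfer
#'
#' Keeps hits passing the e-value cutoff (`evalue <= evalue_cutoff`) and
#' removes close homologs: hits with *more than* `identity_cutoff` percent
#' identity are excluded (strict inequality, so a hit exactly at the cutoff
#' is retained), which guards against annotating a query from its own
#' near-identical homologs.  Self-hits are always removed.  When one
#' subject has several HSPs, only its best-bit-score hit is kept, since
#' templates are genes, not alignments.
#'
#' @param hits Data.frame from [parse_blast_tabular()].
#' @param identity_cutoff Percent identity above which hits are discarded
#'   (gene level default 60, protein level default 30).
#' @param evalue_cutoff Maximum e-value (default 0.1).
#' @param self Optional identifier of the query itself; matching subjects
#'   are dropped.
#' @return The surviving hits, best hit per subject.
#' @export
filter_homologs <- function(hits, identity_cutoff, evalue_cutoff = 0.1,
                            self = NULL) {
  stopifnot(identity_cutoff > 0, identity_cutoff <= 100, evalue_cutoff > 0)
  keep <- hits$evalue <= evalue_cutoff & hits$pident <= identity_cutoff
  if (!is.null(self)) keep <- keep & hits$sseqid != self
  hits <- hits[keep, , drop = FALSE]
  if (!nrow(hits)) return(hits)
  best <- unlist(lapply(split(seq_len(nrow(hits)), hits$sseqid),
                        function(i) i[which.max(hits$bitscore[i])]),
                 use.names = FALSE)
  hits[sort(best), , drop = FALSE]
}

# shared scorer: bit-score weighted term frequency over template genes
.bit_weighted_scores <- function(template_genes, bitscores, annots, aspect) {
  known <- template_genes %in% names(annots$sets[[aspect]])
  if (any(!known))
    warning("dropping ", sum(!known), " template(s) without annotation: ",
            paste(utils::head(unique(template_genes[!known]), 5L),
                  collapse = ", "))
  template_genes <- template_genes[known]
  bitscores <- bitscores[known]
  if (!length(template_genes)) return(stats::setNames(numeric(0), character(0)))
  total <- sum(bitscores)
  acc <- new.env(parent = emptyenv())
  for (k in seq_along(template_genes)) {
    for (tm in annots$sets[[aspect]][[template_genes[k]]]) {
      prev <- if (is.null(acc[[tm]])) 0 else acc[[tm]]
      acc[[tm]] <- prev + bitscores[k]
    }
  }
  terms <- ls(acc)
  stats::setNames(vapply(terms, function(tm) acc[[tm]], 1) / total, terms)
}

#' Bit-score weighted GO transfer from alignment templates
#'
#' Scores each GO term by the bit-score weighted fraction of template genes
#' carrying it: `score(Q) = sum_k b_k I_k(Q) / sum_k b_k`, where `b_k` is
#' the bit-score of the k-th surviving template and `I_k(Q)` indicates
#' whether that template is annotated with Q.  Templates that cannot be
#' resolved to an annotated gene are dropped with a warning.  An empty
#' template list yields an empty score map (no prediction).
#'
#' @param hits Filtered hits (see [filter_homologs()]); `sseqid` must be
#'   gene identifiers present in `annots`.
#' @param annots An [annotation_db].
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @return Named numeric vector of confidences in \[0, 1\].
#' @export
alignment_transfer_score <- function(hits, annots, aspect) {
  .bit_weighted_scores(hits$sseqid, hits$bitscore, annots, aspect)
}

#' Protein-level GO transfer
#'
#' Same bit-score weighted scoring as [alignment_transfer_score()], but the
#' alignment runs in protein space: subject protein ids are mapped back to
#' gene ids through `id_map` before annotation lookup.  Two protein
#' templates mapping to one gene keep their separate bit-scores.  A query
#' without a coding protein cannot use this channel at all; that case is
#' signalled by returning `NULL` (distinct from an empty hit list, which
#' gives an empty score map).
#'
#' @param protein_hits Filtered protein-level hits (identity cutoff t2).
#' @param id_map Data.frame with columns `protein_id`, `gene_id`.
#' @param annots An [annotation_db].
#' @param aspect GO aspect.
#' @param query_protein Protein id of the query, or `NA` for a non-coding
#'   query (returns `NULL`: no prediction possible at this level).
#' @return Named confidence vector, or `NULL` for a non-coding query.
#' @export
psagp_score <- function(protein_hits, id_map, annots, aspect,
                        query_protein = NULL) {
  if (!is.null(query_protein) && is.na(query_protein)) return(NULL)
  mapped <- id_map$gene_id[match(protein_hits$sseqid, id_map$protein_id)]
  miss <- is.na(mapped)
  if (any(miss))
    warning("dropping ", sum(miss), " protein hit(s) absent from the id map")
  .bit_weighted_scores(mapped[!miss], protein_hits$bitscore[!miss],
                       annots, aspect)
}

#' Naive annotation-frequency prior
#'
#' Query-independent prior: each term is scored by the fraction of
#' annotated genes in the aspect carrying it, `N(Q) / N_GO`.
#'
#' @param annots An [annotation_db].
#' @param aspect GO aspect with at least one annotated gene.
#' @return Named numeric vector over the aspect's annotated terms, in
#'   \[0, 1\].
#' @export
ngp_score <- function(annots, aspect) {
  n <- if (aspect %in% names(annots$n_genes))
    annots$n_genes[[aspect]] else 0L
  if (is.na(n) || n == 0L)
    stop("no annotated genes for aspect ", aspect)
  annots$term_count[[aspect]] / n
}

#' Percent identity of two aligned equal-length sequences
#'
#' Columnwise identity of two pre-aligned sequences: `100 * matches /
#' length`.  This backs the synthetic benchmark's alignment fixtures (which
#' are generated as equal-length mutated copies); it is not a pairwise
#' aligner.
#'
#' @param seq_a,seq_b Character scalars of equal nchar.
#' @return Percent identity in \[0, 100\].
#' @export
naive_pairwise_identity <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("sequences differ in length (", nchar(seq_a), " vs ",
         nchar(seq_b), ")")
  a <- strsplit(seq_a, "", fixed = TRUE)[[1L]]
  b <- strsplit(seq_b, "", fixed = TRUE)[[1L]]
  100 * sum(a == b) / length(a)
}
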