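# GO DAG handling: OBO parsing, ancestor propagation, hierarchical score
# post-processing, and set-level functional similarity.

GO_ASPECTS <- c("MF", "BP", "CC")

#' Construct a GO DAG object
#'
#' Builds a validated directed acyclic graph over GO terms from a parent
#' relation.  Each term belongs to one of the three GO aspects (MF, BP, CC);
#' aspects are independent sub-DAGs, each with a single root from which every
#' term of the aspect is reachable via parent edges.
#'
#' @param terms Character vector of term identifiers.
#' @param parents Named list mapping each term to a character vector of its
#'   direct parents (possibly empty).  Terms absent from the list are treated
#'   as parentless.  Cross-aspect edges are dropped.
#' @param aspect Named character vector giving the aspect (`"MF"`, `"BP"` or
#'   `"CC"`) of every term.
#' @return An object of class `go_dag` with elements `terms`, `parents`,
#'   `children`, `aspect`, `roots` (one root id per aspect present) and
#'   `topo` (a topological order, parents before children).
#' @export
go_dag <- function(terms, parents, aspect) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) stop("duplicate term identifiers")
  aspect <- aspect[terms]
  if (anyNA(aspect)) stop("every term needs an aspect")
  bad <- setdiff(unique(aspect), GO_ASPECTS)
  if (length(bad)) stop("unknown aspect(s): ", paste(bad, collapse = ", "))

  par <- stats::setNames(vector("list", length(terms)), terms)
  for (tm in terms) {
    p <- unique(as.character(parents[[tm]]))
    p <- p[p %in% terms]
    p <- p[aspect[p] == aspect[[tm]]]        # drop cross-aspect edges
    par[[tm]] <- p
  }

  chl <- stats::setNames(rep(list(character(0)), length(terms)), terms)
  for (tm in terms) for (p in par[[tm]]) chl[[p]] <- c(chl[[p]], tm)

  topo <- .topological_order(terms, par)      # errors on cycles

  roots <- character(0)
  for (a in intersect(GO_ASPECTS, unique(aspect))) {
    in_a <- terms[aspect == a]
    r <- in_a[vapply(par[in_a], length, 1L) == 0L]
    if (length(r) != 1L)
      stop("aspect ", a, " must have exactly one root, found ", length(r))
    roots[[a]] <- r
  }

  structure(list(terms = terms, parents = par, children = chl,
                 aspect = aspect, roots = roots, topo = topo),
            class = "go_dag")
}

# Kahn's algorithm; parents come before children in the returned order.
.topological_order <- function(terms, parents) {
  indeg <- vapply(parents[terms], length, 1L)
  names(indeg) <- terms
  queue <- terms[indeg == 0L]
  children <- stats::setNames(rep(list(character(0)), length(terms)), terms)
  for (tm in terms) for (p in parents[[tm]])
    children[[p]] <- c(children[[p]], tm)
  out <- character(0)
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    out <- c(out, v)
    for (ch in children[[v]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) stop("ontology graph contains a cycle")
  out
}

#' @export
print.go_dag <- function(x, ...) {
  cat("go_dag:", length(x$terms), "terms;",
      paste(sprintf("%s=%d", names(x$roots),
                    tabulate(factor(x$aspect, names(x$roots)))),
            collapse = " "), "\n")
  invisible(x)
}

#' Read a GO ontology from an OBO flat file
#'
#' Minimal OBO v1.2/1.4 reader covering the fields needed for hierarchical
#' annotation work: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, and `is_obsolete`.  Obsolete terms are dropped
#' with a warning.  Which relationship types count as hierarchy edges is
#' configurable; by default both `is_a` and `part_of` are followed, the
#' common convention for GO ancestor propagation.
#'
#' @param path Path to an OBO file.
#' @param edge_types Character vector of relation types treated as parent
#'   edges.  `"is_a"` covers the `is_a:` tag; any other entry `x` matches
#'   `relationship: x`.
#' @return A [go_dag] object.
#' @export
read_obo <- function(path, edge_types = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  ns_map <- c(molecular_function = "MF", biological_process = "BP",
              cellular_component = "CC")

  ids <- character(0); aspects <- character(0)
  parents <- list(); obsolete <- character(0)
  cur <- NULL; cur_parents <- character(0); cur_ns <- NA_character_
  cur_obs <- FALSE; in_term <- FALSE

  flush <- function() {
    if (is.null(cur)) return()
    if (cur_obs) { obsolete <<- c(obsolete, cur); return() }
    ids <<- c(ids, cur)
    aspects <<- c(aspects, cur_ns)
    parents[[cur]] <<- cur_parents
  }

  for (ln in lines) {
    ln <- sub("!.*$", "", ln)                 # strip trailing comments
    ln <- trimws(ln)
    if (ln == "[Term]") {
      if (in_term) flush()
      in_term <- TRUE
      cur <- NULL; cur_parents <- character(0)
      cur_ns <- NA_character_; cur_obs <- FALSE
      next
    }
    if (grepl("^\\[", ln)) { if (in_term) flush(); in_term <- FALSE; next }
    if (!in_term || ln == "") next
    if (grepl("^id:", ln)) {
      cur <- trimws(sub("^id:", "", ln))
    } else if (grepl("^namespace:", ln)) {
      ns <- trimws(sub("^namespace:", "", ln))
      cur_ns <- if (ns %in% names(ns_map)) ns_map[[ns]] else NA_character_
    } else if (grepl("^is_a:", ln) && "is_a" %in% edge_types) {
      cur_parents <- c(cur_parents, trimws(sub("^is_a:", "", ln)))
    } else if (grepl("^relationship:", ln)) {
      rel <- strsplit(trimws(sub("^relationship:", "", ln)), "\\s+")[[1L]]
      if (length(rel) >= 2L && rel[[1L]] %in% edge_types)
        cur_parents <- c(cur_parents, rel[[2L]])
    } else if (grepl("^is_obsolete:\\s*true", ln)) {
      cur_obs <- TRUE
    }
  }
  if (in_term) flush()

  if (length(obsolete))
    warning("dropped ", length(obsolete), " obsolete term(s): ",
            paste(utils::head(obsolete, 5L), collapse = ", "),
            if (length(obsolete) > 5L) ", ..." else "")
  if (!length(ids)) stop("no terms found in ", path)
  if (anyNA(aspects)) stop("term(s) without a recognised GO namespace")

  # drop edges pointing at obsolete/unknown terms
  parents <- lapply(parents, function(p) p[p %in% ids])
  go_dag(ids, parents, stats::setNames(aspects, ids))
}

.check_terms <- function(terms, dag) {
  unknown <- setdiff(terms, dag$terms)
  if (length(unknown))
    stop("unknown term identifier(s): ", paste(unknown, collapse = ", "))
}

#' Ancestor closure of a term set
#'
#' Augments a set of GO terms with all of their ancestors (direct parents,
#' their parents, and so on up to the aspect root).  An annotation to a term
#' always implies annotation to every ancestor, so both ground-truth and
#' predicted term sets are handled in ancestor-closed form.  Idempotent.
#'
#' @param terms Character vector of term ids present in `dag`.
#' @param dag A [go_dag].
#' @return Character vector: the union of `terms` and all their ancestors,
#'   in DAG topological order.
#' @export
propagate_terms <- function(terms, dag) {
  terms <- unique(as.character(terms))
  .check_terms(terms, dag)
  seen <- stats::setNames(logical(length(dag$terms)), dag$terms)
  queue <- terms
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]
    if (seen[[v]]) next
    seen[[v]] <- TRUE
    queue <- c(queue, dag$parents[[v]])
  }
  dag$topo[seen[dag$topo]]
}

#' Enforce hierarchical consistency of confidence scores
#'
#' Post-processes per-term confidence scores so that every term scores at
#' least as high as each of its children: the output score of a term is the
#' maximum input score over its descendant set (itself included).  This is
#' the standard CAFA-style rule making a prediction set parent-monotone.
#' Idempotent, and never decreases any score.
#'
#' @param scores Named numeric vector (names are term ids in `dag`),
#'   values in \[0, 1\].
#' @param dag A [go_dag].
#' @return Named numeric vector over the same terms, parent-monotone.
#' @export
postprocess_scores <- function(scores, dag) {
  if (is.null(names(scores))) stop("scores must be a named vector")
  .check_terms(names(scores), dag)
  if (any(scores < 0 | scores > 1)) stop("scores must lie in [0, 1]")
  out <- stats::setNames(numeric(length(dag$terms)), dag$terms)
  out[names(scores)] <- scores
  # children before parents: walk reverse topological order
  for (tm in rev(dag$topo)) {
    kids <- dag$children[[tm]]
    if (length(kids)) out[[tm]] <- max(out[[tm]], out[kids])
  }
  out[names(scores)]
}

#' Functional similarity of two GO term sets
#'
#' F1-score overlap between two nonempty term sets: with
#' `p = |a intersect b| / |a|` and `r = |a intersect b| / |b|`, returns
#' `2 p r / (p + r)` (0 when the sets are disjoint).  Symmetric, equals 1
#' iff the sets are identical.  Term sets are expected in ancestor-closed
#' form (set `closed = FALSE` deliberately to compare raw leaf sets).
#'
#' @param a,b Nonempty character vectors of term ids.
#' @param dag Optional [go_dag]; if supplied and `closed = TRUE`, both sets
#'   are ancestor-closed before comparison.
#' @param closed Logical; close the sets over ancestors first (default when
#'   a `dag` is given).
#' @return Similarity in \[0, 1\].
#' @export
functional_similarity <- function(a, b, dag = NULL, closed = !is.null(dag)) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (!length(a) || !length(b))
    stop("functional similarity is undefined for empty term sets")
  if (closed) {
    if (is.null(dag)) stop("closing term sets requires a dag")
    a <- propagate_terms(a, dag); b <- propagate_terms(b, dag)
  }
  inter <- length(intersect(a, b))
  if (inter == 0L) return(0)
  p <- inter / length(a)
  r <- inter / length(b)
  2 * p * r / (p + r)
}

#' Read gene-to-GO annotations from a TSV file
#'
#' Expects columns `gene_id`, `go_id`, `aspect` (header required).  Evidence
#' code filtering, if any, is the caller's concern and happens upstream.
#'
#' @param path Path to a tab-separated annotation file.
#' @return A data.frame with columns `gene_id`, `go_id`, `aspect`.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "go_id", "aspect")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("annotation file lacks column(s): ", paste(miss, collapse = ", "))
  df[need]
}

#' Build an annotation database
#'
#' Stores per-gene, per-aspect GO term sets in ancestor-closed form together
#' with the aggregate counts used by the frequency prior: the number of
#' annotated genes per aspect, and per term the number of genes carrying it.
#'
#' @param annotations Data.frame with columns `gene_id`, `go_id`, `aspect`,
#'   e.g. from [read_annotation_tsv()].
#' @param dag A [go_dag]; all terms must exist in it and the stated aspect
#'   must match the DAG's.
#' @return An object of class `annotation_db` with elements `sets` (list:
#'   aspect -> gene -> character vector of terms, ancestor-closed),
#'   `n_genes` (named integer per aspect) and `term_count` (list: aspect ->
#'   named integer per term).
#' @export
annotation_db <- function(annotations, dag) {
  .check_terms(unique(annotations$go_id), dag)
  stated <- dag$aspect[annotations$go_id]
  if (any(stated != annotations$aspect))
    stop("annotation aspect disagrees with the ontology for term(s): ",
         paste(utils::head(unique(
           annotations$go_id[stated != annotations$aspect]), 5L),
           collapse = ", "))
  sets <- list(); n_genes <- integer(0); term_count <- list()
  for (a in intersect(GO_ASPECTS, unique(annotations$aspect))) {
    sub <- annotations[annotations$aspect == a, , drop = FALSE]
    by_gene <- split(sub$go_id, sub$gene_id)
    sets[[a]] <- lapply(by_gene, propagate_terms, dag = dag)
    n_genes[[a]] <- length(by_gene)
    tc <- table(unlist(sets[[a]], use.names = FALSE))
    term_count[[a]] <- stats::setNames(as.integer(tc), names(tc))
  }
  structure(list(sets = sets, n_genes = n_genes, term_count = term_count),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("annotation_db:",
      paste(sprintf("%s: %d genes / %d terms", names(x$n_genes),
                    x$n_genes, vapply(x$term_count, length, 1L)),
            collapse = "; "), "\n")
  invisible(x)
}

#' Term sets of a set of genes
#'
#' Convenience accessor: ancestor-closed term sets for `genes` in one
#' aspect; genes without annotation get `NULL`.
#'
#' @param annots An [annotation_db].
#' @param genes Character vector of gene ids.
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @return Named list of character vectors.
#' @export
gene_terms <- function(annots, genes, aspect) {
  stats::setNames(annots$sets[[aspect]][genes], genes)
}
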