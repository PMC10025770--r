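# Independent brute-force oracles and small fixture builders shared across
# the suite.  Oracles deliberately use a different algorithmic route than
# the implementation they check.

# random single-rooted DAG: term i > 1 draws 1-2 parents among 1..i-1
rand_dag <- function(n, aspect = "MF") {
  terms <- sprintf("T%03d", seq_len(n))
  parents <- list(T001 = character(0))
  for (i in seq_len(n)[-1L]) {
    k <- min(i - 1L, sample(1:2, 1L))
    parents[[terms[[i]]]] <- terms[sample.int(i - 1L, k)]
  }
  go_dag(terms, parents, stats::setNames(rep(aspect, n), terms))
}

# ancestor closure by repeated direct-parent expansion until fixpoint
oracle_closure <- function(terms, dag) {
  s <- terms
  repeat {
    bigger <- union(s, unlist(dag$parents[s], use.names = FALSE))
    if (length(bigger) == length(s)) return(sort(s))
    s <- bigger
  }
}

# descendant set of each term via the closure oracle run in reverse
oracle_descendants <- function(dag) {
  anc <- lapply(stats::setNames(dag$terms, dag$terms),
                function(tm) oracle_closure(tm, dag))
  lapply(stats::setNames(dag$terms, dag$terms), function(tm)
    dag$terms[vapply(anc, function(a) tm %in% a, TRUE)])
}

# batch-hard loss by exhaustive anchor/positive/negative enumeration
oracle_batch_hard <- function(emb, same, margin) {
  m <- nrow(emb)
  losses <- c()
  for (i in seq_len(m)) {
    pos <- setdiff(which(same[i, ]), i)
    neg <- setdiff(which(!same[i, ]), i)
    if (!length(pos) || !length(neg)) next
    best <- 0
    for (p in pos) for (q in neg)
      best <- max(best, triplet_loss_single(
        pairwise_distance(emb[i, ], emb[p, ]),
        pairwise_distance(emb[i, ], emb[q, ]), margin))
    losses <- c(losses, best)
  }
  if (!length(losses)) 0 else mean(losses)
}

# AUPRC by explicit threshold sweep over flattened (gene, term) pairs
oracle_auprc <- function(predictions, truth) {
  scores <- c(); labels <- c()
  for (g in names(truth)) {
    terms <- union(names(predictions[[g]]), truth[[g]])
    s <- stats::setNames(numeric(length(terms)), terms)
    s[names(predictions[[g]])] <- predictions[[g]]
    scores <- c(scores, unname(s))
    labels <- c(labels, terms %in% truth[[g]])
  }
  ts <- sort(unique(scores), decreasing = TRUE)
  pr <- rc <- numeric(length(ts))
  for (i in seq_along(ts)) {
    sel <- scores >= ts[[i]]
    pr[[i]] <- sum(labels[sel]) / sum(sel)
    rc[[i]] <- sum(labels[sel]) / sum(labels)
  }
  sum(diff(c(0, rc)) * pr)
}

# Eq.-style bit-score transfer by direct double loop
oracle_transfer <- function(hits, annots, aspect) {
  terms <- unique(unlist(annots$sets[[aspect]][hits$sseqid]))
  out <- stats::setNames(numeric(length(terms)), terms)
  for (tm in terms) {
    num <- 0
    for (k in seq_len(nrow(hits)))
      if (tm %in% annots$sets[[aspect]][[hits$sseqid[[k]]]])
        num <- num + hits$bitscore[[k]]
    out[[tm]] <- num / sum(hits$bitscore)
  }
  out
}

# rank-weighted GBA transfer in an arbitrary distance space (baseline)
rank_transfer <- function(d, labels, K) {
  nearest <- order(d)[seq_len(K)]
  w <- 1 - (seq_len(K) - 1) / K
  drop(w %*% labels[nearest, , drop = FALSE]) / sum(w)
}

# tiny two-class annotation fixture over a 5-term DAG
tiny_annotated <- function() {
  terms <- c("R", "A", "B", "a1", "b1")
  parents <- list(R = character(0), A = "R", B = "R", a1 = "A", b1 = "B")
  dag <- go_dag(terms, parents,
                stats::setNames(rep("MF", 5L), terms))
  ann <- data.frame(
    gene_id = sprintf("g%02d", 1:8),
    go_id = rep(c("a1", "b1"), each = 4L),
    aspect = "MF", stringsAsFactors = FALSE)
  list(dag = dag, ann = ann, annots = annotation_db(ann, dag))
}

# small expression fixture matching tiny_annotated's two classes
tiny_expression <- function(seed = 5L, l = 12L) {
  set.seed(seed)
  centroids <- rbind(c(rep(4, l / 2), rep(0, l / 2)),
                     c(rep(0, l / 2), rep(4, l / 2)))
  cls <- rep(1:2, each = 4L)
  values <- centroids[cls, ] + matrix(rnorm(8 * l, sd = 0.5), 8L, l)
  expression_matrix(values, sprintf("g%02d", 1:8),
                    sprintf("s%02d", seq_len(l)))
}

quick_tnp_config <- function(seed = 1L, epochs = 10, ...) {
  tnp_config(layers = c(16, 8), epochs = epochs, K = 3,
             batch_classes = 2, batch_per_class = 3, seed = seed, ...)
}
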