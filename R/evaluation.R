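# CAFA-style evaluation: pooled precision/recall, Fmax, AUPRC,
# species-weighted averages, rank-weighted functional similarity, and
# term-centric AUROC.
#
# Predictions are a named list gene -> named confidence vector; truth is a
# named list gene -> character vector of (ancestor-closed) GO terms.  Only
# genes present in `truth` are evaluated.

.eval_counts <- function(predictions, truth, t) {
  tp <- 0; fp <- 0; fn <- 0; predicted_any <- FALSE
  for (g in names(truth)) {
    pred <- predictions[[g]]
    hit <- if (is.null(pred)) character(0) else names(pred)[pred >= t]
    if (length(hit)) predicted_any <- TRUE
    tp_g <- length(intersect(hit, truth[[g]]))
    tp <- tp + tp_g
    fp <- fp + length(hit) - tp_g
    fn <- fn + length(truth[[g]]) - tp_g
  }
  list(tp = tp, fp = fp, fn = fn, predicted_any = predicted_any)
}

#' Pooled precision and recall at a confidence threshold
#'
#' Counts true/false positives and false negatives pooled over all
#' evaluated genes for predictions with confidence `>= t`:
#' `pr = tp / (tp + fp)`, `rc = tp / (tp + fn)`.  Genes with no prediction
#' at the threshold contribute nothing to precision's denominator (their
#' missed terms still count as false negatives); when no gene predicts
#' anything, precision is `NA` (no-prediction state) and recall is 0.
#'
#' @param predictions Named list: gene -> named confidence vector.
#' @param truth Named list: gene -> character vector of true terms
#'   (ancestor-closed).
#' @param t Threshold in \[0, 1\].
#' @return List with elements `pr` and `rc`.
#' @export
precision_recall_at <- function(predictions, truth, t) {
  if (t < 0 || t > 1) stop("threshold must lie in [0, 1]")
  ct <- .eval_counts(predictions, truth, t)
  pr <- if (ct$tp + ct$fp > 0) ct$tp / (ct$tp + ct$fp)
        else if (ct$predicted_any) 1 else NA_real_
  rc <- if (ct$tp + ct$fn > 0) ct$tp / (ct$tp + ct$fn) else NA_real_
  list(pr = pr, rc = rc)
}

#' Maximum F1 over confidence thresholds (Fmax)
#'
#' Sweeps a threshold grid made of every distinct predicted confidence plus
#' 0 and 1 (exact maximization, no discretization error), computes pooled
#' precision/recall at each, and returns the maximum harmonic mean together
#' with the maximizing threshold.
#'
#' @inheritParams precision_recall_at
#' @return List with `fmax`, `threshold`, and the swept `curve`
#'   (data.frame of t, pr, rc).
#' @export
fmax <- function(predictions, truth) {
  if (!length(truth) || !sum(lengths(truth)))
    stop("empty ground truth")
  grid <- sort(unique(c(0, 1,
    unlist(lapply(predictions[names(truth)], unname), use.names = FALSE))))
  grid <- grid[grid >= 0 & grid <= 1]
  best <- 0; best_t <- 0
  curve <- data.frame(t = grid, pr = NA_real_, rc = NA_real_)
  for (i in seq_along(grid)) {
    pc <- precision_recall_at(predictions, truth, grid[[i]])
    curve$pr[[i]] <- pc$pr; curve$rc[[i]] <- pc$rc
    if (!is.na(pc$pr) && !is.na(pc$rc) && pc$pr + pc$rc > 0) {
      f1 <- 2 * pc$pr * pc$rc / (pc$pr + pc$rc)
      if (f1 > best) { best <- f1; best_t <- grid[[i]] }
    }
  }
  list(fmax = best, threshold = best_t, curve = curve)
}

#' Area under the precision-recall curve
#'
#' Flattens predictions over (gene, term) pairs — for each evaluated gene,
#' the union of its scored terms and its true terms, unscored true terms
#' entering at confidence 0 — and integrates the precision-recall curve
#' with step interpolation over all distinct thresholds.
#'
#' @inheritParams precision_recall_at
#' @return Area in \[0, 1\].
#' @export
auprc <- function(predictions, truth) {
  scores <- numeric(0); labels <- integer(0)
  for (g in names(truth)) {
    pred <- predictions[[g]]
    terms <- union(names(pred), truth[[g]])
    s <- stats::setNames(numeric(length(terms)), terms)
    if (!is.null(pred)) s[names(pred)] <- pred
    scores <- c(scores, unname(s))
    labels <- c(labels, as.integer(terms %in% truth[[g]]))
  }
  n_pos <- sum(labels)
  if (n_pos == 0L) stop("no positive (gene, term) pairs in the truth")
  ord <- order(scores, decreasing = TRUE)
  scores <- scores[ord]; labels <- labels[ord]
  tp <- cumsum(labels)
  fp <- cumsum(1L - labels)
  # evaluate at the last index of each distinct score (all pairs >= t)
  last <- which(diff(scores) != 0)
  idx <- c(last, length(scores))
  pr <- tp[idx] / (tp[idx] + fp[idx])
  rc <- tp[idx] / n_pos
  sum(diff(c(0, rc)) * pr)
}

#' Weighted average across species
#'
#' `sum(v_i N_i) / sum(N_i)`: the gene-count-weighted mean used to average
#' per-species Fmax or AUPRC into a single figure.
#'
#' @param values Numeric vector of per-species metric values.
#' @param counts Positive gene counts, same length.
#' @return Weighted mean.
#' @export
weighted_average <- function(values, counts) {
  if (!length(values)) stop("no values to average")
  if (length(values) != length(counts) || any(counts <= 0))
    stop("counts must be positive and match values")
  sum(values * counts) / sum(counts)
}

#' Rank-weighted functional similarity of a template list (WFS)
#'
#' For a query's K ranked templates with functional similarities `FS_i`
#' (rank 1 = most similar expression), the i-th template gets weight
#' `w_i = 1 - (r_i - 1) / K` and the diagnostic is
#' `sum(w_i FS_i) / sum(w_i)`.  High values mean the expression-similarity
#' ranking tracks functional similarity.
#'
#' @param fs Numeric vector of functional similarities in rank order
#'   (length K >= 1), values in \[0, 1\].
#' @return Weighted similarity in \[0, 1\].
#' @export
wfs <- function(fs) {
  K <- length(fs)
  if (K == 0L) stop("WFS needs at least one template")
  w <- 1 - (seq_len(K) - 1) / K
  sum(w * fs) / sum(w)
}

#' Average WFS over test genes
#'
#' @param wfs_values Numeric vector of per-gene [wfs()] values.
#' @return Their mean.
#' @export
avg_wfs <- function(wfs_values) {
  if (!length(wfs_values)) stop("no WFS values")
  mean(wfs_values)
}

#' Term-centric AUROC
#'
#' Rank-based (Mann-Whitney) area under the ROC curve for one GO term:
#' the probability that a randomly chosen annotated gene outscores a
#' randomly chosen unannotated one, with average-rank tie correction.
#'
#' @param scores Numeric confidence per gene for the term.
#' @param labels Binary vector; both classes must be present.
#' @return AUROC in \[0, 1\].
#' @export
term_auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC is undefined without both classes")
  r <- rank(scores)                       # average ranks correct ties
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate a prediction set
#'
#' Convenience wrapper computing Fmax (with its threshold) and AUPRC for
#' one aspect's predictions against ancestor-closed truth.
#'
#' @inheritParams precision_recall_at
#' @return List with `fmax`, `threshold`, `auprc`, `n_genes`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  fm <- fmax(predictions, truth)
  list(fmax = fm$fmax, threshold = fm$threshold,
       auprc = auprc(predictions, truth), n_genes = length(truth))
}
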