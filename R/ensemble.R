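# Consensus scoring: a one-layer logistic combiner over the per-term
# confidences of the component methods (expression, gene alignment,
# protein alignment, frequency prior).

ALL_METHODS <- c("EPGP", "GSAGP", "PSAGP", "NGP")

#' Train a score combiner
#'
#' Fits a single fully connected layer with sigmoid output (a logistic
#' model) mapping the per-(gene, term) confidence vector of the selected
#' component methods to a consensus confidence.  Trained by full-batch
#' gradient descent on binary cross-entropy; weights start at zero (output
#' 0.5 everywhere) and the run is reproducible under `seed`.  One combiner
#' is shared across all terms of an aspect.
#'
#' @param x Numeric matrix, one row per (gene, term) training example and
#'   one column per method score in \[0, 1\]; missing (masked) methods
#'   carry 0.
#' @param y Binary vector: 1 when the gene is truly annotated with the term
#'   (ancestor-closed truth).  Must contain both classes.
#' @param methods Character vector naming the columns of `x`, a subset of
#'   `c("EPGP", "GSAGP", "PSAGP", "NGP")`.
#' @param iterations,learning_rate Gradient-descent schedule (defaults
#'   2000 steps at 0.1).
#' @param seed Integer seed (recorded; training itself is deterministic
#'   from the zero start).
#' @return An object of class `combiner_model` with `weights`, `bias`,
#'   `methods`, and training metadata.
#' @export
train_combiner <- function(x, y, methods = colnames(x),
                           iterations = 2000, learning_rate = 0.1,
                           seed = 1L) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (is.null(methods)) stop("method names are required")
  bad <- setdiff(methods, ALL_METHODS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (!length(methods)) stop("method subset must be nonempty")
  if (ncol(x) != length(methods)) stop("x must have one column per method")
  if (nrow(x) != length(y)) stop("x and y disagree in length")
  if (all(y == 0) || all(y == 1))
    stop("combiner training needs both positive and negative examples")
  set.seed(seed)
  w <- numeric(ncol(x)); b <- 0
  n <- length(y)
  for (it in seq_len(iterations)) {
    p <- .sigmoid(drop(x %*% w) + b)
    g <- (p - y) / n                      # d BCE / d logit
    w <- w - learning_rate * drop(crossprod(x, g))
    b <- b - learning_rate * sum(g)
  }
  structure(list(weights = stats::setNames(w, methods), bias = b,
                 methods = methods, iterations = iterations,
                 learning_rate = learning_rate, seed = seed),
            class = "combiner_model")
}

#' @export
print.combiner_model <- function(x, ...) {
  cat("combiner_model over {", paste(x$methods, collapse = ", "),
      "}; weights ", paste(signif(x$weights, 3), collapse = ", "),
      "; bias ", signif(x$bias, 3), "\n", sep = "")
  invisible(x)
}

#' Apply a combiner to method scores
#'
#' Consensus confidence `sigmoid(w . x + b)` for each row of method scores.
#' Rows must follow the combiner's method order; masked entries carry 0.
#' Apply [postprocess_scores()] per gene downstream before evaluation.
#'
#' @param model A [train_combiner()] model.
#' @param x Numeric vector (one example) or matrix (examples in rows) with
#'   one entry per model method.
#' @return Consensus confidences in (0, 1).
#' @export
combine_scores <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$methods))
    stop("expected ", length(model$methods), " method columns")
  drop(.sigmoid(drop(x %*% model$weights) + model$bias))
}

#' Select the method subset of a combiner
#'
#' Validates and normalizes a method-subset specification (e.g. the full
#' `EGPN` set or the `EGN` set used for non-coding genes, which lack a
#' protein-level score).  Single-letter shorthand is accepted:
#' `"EGPN"` = EPGP + GSAGP + PSAGP + NGP, `"EGN"` = EPGP + GSAGP + NGP, etc.
#'
#' @param methods Character vector of method names, or a single shorthand
#'   string of letters from E, G, P, N.
#' @return Character vector of validated method names in canonical order.
#' @export
select_subset <- function(methods) {
  if (length(methods) == 1L && !methods %in% ALL_METHODS &&
      grepl("^[EGPN]+$", methods)) {
    letters_ <- strsplit(methods, "")[[1L]]
    methods <- c(E = "EPGP", G = "GSAGP", P = "PSAGP", N = "NGP")[letters_]
  }
  methods <- unique(as.character(methods))
  bad <- setdiff(methods, ALL_METHODS)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (!length(methods)) stop("method subset must be nonempty")
  ALL_METHODS[ALL_METHODS %in% methods]
}
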