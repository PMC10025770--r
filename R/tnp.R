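# Expression-profile pipeline, part 1: normalization, embedding distance,
# and the loss primitives of the triplet network.

#' Construct an expression matrix object
#'
#' Wraps a genes x samples real matrix with identifier checks.  Rows are
#' gene expression profiles across `l` experimental samples.
#'
#' @param values Numeric matrix, genes in rows.
#' @param gene_ids,sample_ids Optional identifier vectors; taken from
#'   dimnames when missing.
#' @return A numeric matrix of class `expression_matrix` with row and
#'   column names set.
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids))
    stop("gene and sample identifiers are required")
  if (anyNA(values)) stop("expression matrix contains missing values; ",
                          "impute or drop rows before construction")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  dimnames(values) <- list(as.character(gene_ids), as.character(sample_ids))
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Read an expression matrix from TSV/CSV
#'
#' Genes in rows (first column = gene id), header row = sample ids.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` -> comma, otherwise tab).
#' @return An [expression_matrix].
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_matrix(as.matrix(df))
}

#' Fit the z-score + PCA normalizer
#'
#' Each sample column is centred and scaled to unit variance, then PCA
#' reduces the `l` sample dimensions to `h` principal components, the input
#' space of the embedding network.  Zero-variance columns get sd 1 (the
#' column becomes all-zero after centring) rather than being dropped.
#'
#' @param expr An [expression_matrix] (m genes x l samples), m >= 2.
#' @param h Number of components to retain, or `NULL` to pick the smallest
#'   `h` whose cumulative explained variance reaches `variance`.
#' @param variance Cumulative variance target used when `h` is `NULL`
#'   (default 0.95).
#' @return An object of class `tnp_normalizer`: `center`, `scale` (length-l),
#'   `rotation` (l x h orthonormal), `h`, `sdev` (all singular sdevs).
#' @export
fit_normalizer <- function(expr, h = NULL, variance = 0.95) {
  x <- unclass(expr)
  if (nrow(x) < 2L) stop("need at least two genes to fit the normalizer")
  ctr <- colMeans(x)
  scl <- apply(x, 2L, stats::sd)
  zero <- scl == 0 | !is.finite(scl)
  if (any(zero)) {
    warning(sum(zero), " zero-variance sample column(s); sd set to 1")
    scl[zero] <- 1
  }
  z <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  hmax <- min(nrow(x) - 1L, ncol(x))
  if (is.null(h)) {
    ev <- pc$sdev^2
    cum <- cumsum(ev) / sum(ev)
    h <- which(cum >= variance)[1L]
    if (is.na(h)) h <- hmax
  }
  h <- min(as.integer(h), hmax)
  if (h < 1L) stop("h must be at least 1")
  structure(list(center = ctr, scale = scl,
                 rotation = pc$rotation[, seq_len(h), drop = FALSE],
                 sdev = pc$sdev, h = h),
            class = "tnp_normalizer")
}

#' Apply a fitted normalizer
#'
#' Projects raw expression rows into the fitted h-dimensional PCA space:
#' `((x - center) / scale) %*% rotation`.  Deterministic.
#'
#' @param state A `tnp_normalizer` from [fit_normalizer()].
#' @param x Numeric vector (one profile) or matrix (profiles in rows) with
#'   the same number of sample columns the state was fitted on.
#' @return Matrix of h-dimensional normalized profiles (one row per input).
#' @export
apply_normalizer <- function(state, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(state$center))
    stop("profile has ", ncol(x), " samples but the normalizer was fitted ",
         "on ", length(state$center))
  z <- sweep(sweep(x, 2L, state$center), 2L, state$scale, "/")
  z %*% state$rotation
}

#' Normalized squared embedding distance
#'
#' Distance between two unit-L2-norm embedding rows:
#' `d = sum_k (u_k - v_k)^2 / 4`.  The division by 4 maps the squared
#' Euclidean distance on the unit sphere into \[0, 1\]; the maximum 1 is
#' attained exactly at antipodal vectors.
#'
#' @param u,v Unit-norm numeric vectors of equal length.
#' @return Distance in \[0, 1\].
#' @export
pairwise_distance <- function(u, v) {
  if (length(u) != length(v)) stop("embedding dimensions differ")
  if (abs(sum(u^2) - 1) > 1e-3 || abs(sum(v^2) - 1) > 1e-3)
    stop("pairwise_distance expects unit-norm embeddings")
  sum((u - v)^2) / 4
}

# All-pairs version used in training/prediction: rows of a, b unit-norm.
.distance_matrix <- function(a, b = a) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmin(pmax(d2 / 4, 0), 1)
}

#' Single-triplet loss
#'
#' `max(d_pos + margin - d_neg, 0)`: zero exactly when the anchor-negative
#' distance exceeds the anchor-positive distance by at least the margin.
#'
#' @param d_pos Anchor-positive embedding distance.
#' @param d_neg Anchor-negative embedding distance.
#' @param margin Positive margin.
#' @return Non-negative loss.
#' @export
triplet_loss_single <- function(d_pos, d_neg, margin) {
  stopifnot(is.finite(d_pos), is.finite(d_neg), is.finite(margin),
            margin > 0)
  max(d_pos + margin - d_neg, 0)
}

#' Batch-hard triplet loss
#'
#' For each anchor in the batch, takes its farthest in-batch positive and
#' nearest in-batch negative ("batch on hard" mining) and accumulates
#' `max(d_pos_max + margin - d_neg_min, 0)`; the result is the mean over
#' anchors that have at least one positive and one negative.  Positives and
#' negatives are defined by the `same` relation (functional similarity above
#' the pairing cutoff); the diagonal is never a positive or a negative.
#'
#' @param embeddings Matrix of unit-norm embedding rows (one per gene).
#' @param same Logical matrix, `same[i, j]` true when genes i and j share
#'   function.  Must be symmetric; the diagonal is ignored.
#' @param margin Positive margin.
#' @return Non-negative loss; 0 with a warning when no anchor contributes.
#' @export
batch_hard_loss <- function(embeddings, same, margin) {
  m <- nrow(embeddings)
  stopifnot(nrow(same) == m, ncol(same) == m, margin > 0)
  d <- .distance_matrix(embeddings)
  pos <- same; diag(pos) <- FALSE
  neg <- !same; diag(neg) <- FALSE
  total <- 0; n_anchor <- 0L
  for (i in seq_len(m)) {
    if (!any(pos[i, ]) || !any(neg[i, ])) next
    total <- total + max(max(d[i, pos[i, ]]) + margin - min(d[i, neg[i, ]]), 0)
    n_anchor <- n_anchor + 1L
  }
  if (n_anchor == 0L) {
    warning("no anchor with both a positive and a negative in the batch")
    return(0)
  }
  total / n_anchor
}

#' Multi-label cross-entropy loss
#'
#' `-sum_ij [y log s + (1 - y) log(1 - s)] / (r m)` over an m x r score
#' matrix and binary label matrix; scores are clipped to
#' \[1e-7, 1 - 1e-7\] before the logs.
#'
#' @param scores Numeric m x r matrix of confidences in (0, 1).
#' @param labels Binary m x r matrix.
#' @return Non-negative mean cross-entropy.
#' @export
cross_entropy_loss <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  if (!all(dim(scores) == dim(labels)))
    stop("scores and labels have different shapes")
  eps <- 1e-7
  s <- pmin(pmax(scores, eps), 1 - eps)
  -sum(labels * log(s) + (1 - labels) * log(1 - s)) / length(s)
}

#' Combined training loss
#'
#' Triplet term plus `alpha` times the cross-entropy term.
#'
#' @param triplet Batch-hard triplet loss value.
#' @param ce Cross-entropy loss value.
#' @param alpha Non-negative trade-off weight.
#' @return `triplet + alpha * ce`.
#' @export
training_loss <- function(triplet, ce, alpha) {
  stopifnot(triplet >= 0, ce >= 0, alpha >= 0)
  triplet + alpha * ce
}

#' Configuration of the triplet-network pipeline
#'
#' @param margin Triplet margin on the normalized distance scale (default
#'   0.2).
#' @param alpha Weight of the cross-entropy term in the training loss
#'   (default 1).
#' @param w Blend weight between the rank-transfer branch and the sigmoid
#'   output branch at prediction time, in \[0, 1\] (default 0.5).
#' @param cf Functional-similarity cutoff: two genes pair as positives when
#'   their GO-set F1 exceeds `cf` strictly (default 0.5).
#' @param K Neighbour count of the rank-transfer branch (default 100;
#'   capped at the training-set size when applied).
#' @param layers Widths of the fully connected embedding block (default
#'   `c(1024, 1024)`, ReLU activations).
#' @param epochs,batch_classes,batch_per_class Training schedule: number of
#'   passes, and the stratified batch composition (P classes x Q genes,
#'   defaults 8 x 4, resampling with replacement within small classes).
#' @param learning_rate Adam step size (default 1e-3).
#' @param seed Integer seed governing initialization and batch sampling.
#' @return A list of class `tnp_config`.
#' @export
tnp_config <- function(margin = 0.2, alpha = 1, w = 0.5, cf = 0.5, K = 100,
                       layers = c(1024, 1024), epochs = 30,
                       batch_classes = 8, batch_per_class = 4,
                       learning_rate = 1e-3, seed = 1L) {
  stopifnot(margin > 0, alpha >= 0, w >= 0, w <= 1, cf > 0, cf < 1,
            K >= 1, length(layers) >= 1, all(layers >= 1), epochs >= 1,
            learning_rate > 0)
  structure(list(margin = margin, alpha = alpha, w = w, cf = cf,
                 K = as.integer(K), layers = as.integer(layers),
                 epochs = as.integer(epochs),
                 batch_classes = as.integer(batch_classes),
                 batch_per_class = as.integer(batch_per_class),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "tnp_config")
}
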