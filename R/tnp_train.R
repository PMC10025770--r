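# Expression-profile pipeline, part 2: the embedding network, its
# training loop, and the two-branch prediction.
#
# The network is a deep fully connected block (DFCB) of ReLU layers mapping
# the h-dimensional normalized profile to a d_N-dimensional embedding, which
# is L2-normalized for the metric branch; a sigmoid output layer attached to
# the DFCB output provides per-term confidences for the classification
# branch.  Both branches are trained jointly: batch-hard triplet loss on the
# embeddings plus alpha * cross-entropy on the sigmoid scores, minimized by
# Adam.  All linear algebra is plain R matrix arithmetic with analytic
# gradients, which keeps training bitwise-reproducible under one seed.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

.l2_rows <- function(u) {
  nrm <- sqrt(rowSums(u^2))
  weak <- nrm < 1e-12
  if (any(weak)) {
    warning("near-zero embedding row(s); epsilon added before normalization")
    u[weak, ] <- u[weak, , drop = FALSE] + 1e-8
    nrm <- sqrt(rowSums(u^2))
  }
  list(un = u / nrm, norm = nrm)
}

# forward pass through the DFCB; returns activations of every layer
.forward <- function(params, x) {
  a <- list(x)
  z <- list()
  for (k in seq_along(params$W)) {
    z[[k]] <- sweep(a[[k]] %*% params$W[[k]], 2L, params$b[[k]], "+")
    a[[k + 1L]] <- pmax(z[[k]], 0)
  }
  dfcb <- a[[length(a)]]
  l2 <- .l2_rows(dfcb)
  scores <- .sigmoid(sweep(dfcb %*% params$Wo, 2L, params$bo, "+"))
  list(a = a, z = z, dfcb = dfcb, un = l2$un, norm = l2$norm,
       scores = scores)
}

# gradient of the batch-hard triplet loss w.r.t. the L2-normalized
# embeddings; mirrors batch_hard_loss() exactly
.batch_hard_grad <- function(un, same, margin) {
  m <- nrow(un)
  d <- .distance_matrix(un)
  pos <- same; diag(pos) <- FALSE
  neg <- !same; diag(neg) <- FALSE
  g <- matrix(0, m, ncol(un))
  loss <- 0; n_anchor <- 0L
  for (i in seq_len(m)) {
    if (!any(pos[i, ]) || !any(neg[i, ])) next
    jp <- which(pos[i, ])[which.max(d[i, pos[i, ]])]
    jn <- which(neg[i, ])[which.min(d[i, neg[i, ]])]
    n_anchor <- n_anchor + 1L
    val <- d[i, jp] + margin - d[i, jn]
    if (val <= 0) next
    loss <- loss + val
    # d(i,j) = |u_i - u_j|^2 / 4  =>  grad_{u_i} = (u_i - u_j) / 2
    g[i, ] <- g[i, ] + (un[jn, ] - un[jp, ]) / 2
    g[jp, ] <- g[jp, ] + (un[jp, ] - un[i, ]) / 2
    g[jn, ] <- g[jn, ] - (un[jn, ] - un[i, ]) / 2
  }
  if (n_anchor == 0L) return(list(loss = 0, grad = g, anchors = 0L))
  list(loss = loss / n_anchor, grad = g / n_anchor, anchors = n_anchor)
}

.adam_new <- function(params) {
  lapply(params, function(p)
    list(m = p * 0, v = p * 0))
}

.adam_step <- function(p, g, st, lr, t, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * g
  st$v <- beta2 * st$v + (1 - beta2) * g^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
}

# flatten/unflatten parameter lists for the Adam bookkeeping
.flatten_params <- function(params) {
  c(stats::setNames(params$W, paste0("W", seq_along(params$W))),
    stats::setNames(params$b, paste0("b", seq_along(params$b))),
    list(Wo = params$Wo, bo = params$bo))
}

#' Train the triplet-network expression model
#'
#' Fits the full expression-profile pipeline for one GO aspect: z-score +
#' PCA normalization, the ReLU embedding block trained with batch-hard
#' triplet loss plus weighted cross-entropy (Adam), and the stored training
#' embeddings/annotations that back the rank-transfer prediction branch.
#'
#' Two training genes count as same-function when the F1 similarity of
#' their ancestor-closed GO sets exceeds `config$cf` strictly.  Batches are
#' stratified: `batch_classes` annotation classes x `batch_per_class` genes,
#' resampled with replacement inside small classes.  A single integer seed
#' governs initialization and batch sampling, so identical inputs and seed
#' reproduce the weights exactly.
#'
#' @param expr An [expression_matrix] containing (at least) the annotated
#'   training genes.
#' @param annots An [annotation_db].
#' @param aspect `"MF"`, `"BP"` or `"CC"`.
#' @param config A [tnp_config()].
#' @param h Optional PCA dimensionality forwarded to [fit_normalizer()].
#' @return An object of class `tnp_model`: normalizer, layer weights,
#'   output-layer weights, `label_vocab` (the r training GO terms),
#'   training-gene embeddings and label matrix, per-epoch `loss_history`,
#'   and the config.
#' @export
train_tnp <- function(expr, annots, aspect, config = tnp_config(),
                      h = NULL) {
  genes <- intersect(rownames(expr), names(annots$sets[[aspect]]))
  if (length(genes) < 2L) stop("need at least two annotated training genes")
  term_sets <- annots$sets[[aspect]][genes]

  # same-function relation under the cf cutoff
  m <- length(genes)
  same <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1L)) for (j in seq.int(i + 1L, m)) {
    fs <- functional_similarity(term_sets[[i]], term_sets[[j]])
    same[i, j] <- same[j, i] <- fs > config$cf
  }
  diag(same) <- TRUE
  if (all(same)) stop("all training genes share function under cf = ",
                      config$cf, "; no negatives exist")

  normalizer <- fit_normalizer(expr[genes, , drop = FALSE], h = h)
  x <- apply_normalizer(normalizer, unclass(expr)[genes, , drop = FALSE])

  vocab <- sort(unique(unlist(term_sets, use.names = FALSE)))
  y <- matrix(0, m, length(vocab), dimnames = list(genes, vocab))
  for (i in seq_len(m)) y[i, term_sets[[i]]] <- 1

  set.seed(config$seed)
  dims <- c(ncol(x), config$layers)
  params <- list(
    W = lapply(seq_len(length(dims) - 1L),
               function(k) .he_init(dims[k], dims[k + 1L])),
    b = lapply(config$layers, function(d) numeric(d)),
    Wo = .he_init(dims[length(dims)], length(vocab)),
    bo = numeric(length(vocab)))

  # exact-set annotation classes drive the stratified batch sampler
  class_id <- vapply(term_sets, function(s) paste(sort(s), collapse = "|"),
                     "")
  by_class <- split(seq_len(m), class_id)
  batch_size <- config$batch_classes * config$batch_per_class
  n_batches <- max(1L, ceiling(m / batch_size))

  adam <- list(
    W = lapply(params$W, function(p) list(m = p * 0, v = p * 0)),
    b = lapply(params$b, function(p) list(m = p * 0, v = p * 0)),
    Wo = list(m = params$Wo * 0, v = params$Wo * 0),
    bo = list(m = params$bo * 0, v = params$bo * 0))
  step <- 0L
  loss_history <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    epoch_loss <- 0
    for (bi in seq_len(n_batches)) {
      cls <- sample(names(by_class),
                    min(config$batch_classes, length(by_class)))
      idx <- unlist(lapply(by_class[cls], function(members)
        sample(members, config$batch_per_class,
               replace = length(members) < config$batch_per_class)),
        use.names = FALSE)
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      sb <- same[idx, idx, drop = FALSE]

      fwd <- .forward(params, xb)
      tri <- .batch_hard_grad(fwd$un, sb, config$margin)
      ce <- cross_entropy_loss(fwd$scores, yb)
      epoch_loss <- epoch_loss +
        training_loss(tri$loss, ce, config$alpha) / n_batches

      # back through L2 normalization: u = a / |a|
      gun <- tri$grad
      dotp <- rowSums(gun * fwd$un)
      g_dfcb <- (gun - fwd$un * dotp) / fwd$norm
      # classification branch: d(alpha * CE)/d logits = alpha (s - y)/(r m)
      gzo <- config$alpha * (fwd$scores - yb) / length(yb)
      gWo <- crossprod(fwd$dfcb, gzo)
      gbo <- colSums(gzo)
      g_dfcb <- g_dfcb + tcrossprod(gzo, params$Wo)

      nl <- length(params$W)
      gW <- vector("list", nl); gb <- vector("list", nl)
      ga <- g_dfcb
      for (k in rev(seq_len(nl))) {
        gz <- ga * (fwd$z[[k]] > 0)
        gW[[k]] <- crossprod(fwd$a[[k]], gz)
        gb[[k]] <- colSums(gz)
        if (k > 1L) ga <- tcrossprod(gz, params$W[[k]])
      }

      step <- step + 1L
      for (k in seq_len(nl)) {
        up <- .adam_step(params$W[[k]], gW[[k]], adam$W[[k]],
                         config$learning_rate, step)
        params$W[[k]] <- up$p; adam$W[[k]] <- up$st
        up <- .adam_step(params$b[[k]], gb[[k]], adam$b[[k]],
                         config$learning_rate, step)
        params$b[[k]] <- up$p; adam$b[[k]] <- up$st
      }
      up <- .adam_step(params$Wo, gWo, adam$Wo, config$learning_rate, step)
      params$Wo <- up$p; adam$Wo <- up$st
      up <- .adam_step(params$bo, gbo, adam$bo, config$learning_rate, step)
      params$bo <- up$p; adam$bo <- up$st
    }
    loss_history[[epoch]] <- epoch_loss
  }

  fwd <- .forward(params, x)
  structure(list(normalizer = normalizer, W = params$W, b = params$b,
                 Wo = params$Wo, bo = params$bo, label_vocab = vocab,
                 genes = genes, train_embeddings = fwd$un,
                 train_labels = y, aspect = aspect, config = config,
                 loss_history = loss_history),
            class = "tnp_model")
}

#' @export
print.tnp_model <- function(x, ...) {
  cat("tnp_model [", x$aspect, "]: ", length(x$genes), " genes, ",
      length(x$label_vocab), " terms, layers ",
      paste(x$config$layers, collapse = "-"), "; final loss ",
      signif(utils::tail(x$loss_history, 1L), 4), "\n", sep = "")
  invisible(x)
}

#' Embed expression profiles
#'
#' Runs profiles through the trained embedding block and L2-normalizes the
#' result, so every output row has unit norm and distances live on the
#' \[0, 1\] normalized scale of [pairwise_distance()].
#'
#' @param model A [train_tnp()] model.
#' @param x Profiles: raw rows over the training sample columns (default)
#'   or already-normalized h-dimensional rows if `normalized = TRUE`.
#' @param normalized Logical; set when `x` is already in PCA space.
#' @return Matrix of unit-norm embedding rows.
#' @export
tnp_embed <- function(model, x, normalized = FALSE) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (!normalized) x <- apply_normalizer(model$normalizer, x)
  .forward(model[c("W", "b", "Wo", "bo")], as.matrix(x))$un
}

#' Rank-weighted annotation transfer from embedding neighbours
#'
#' The metric branch of prediction: the K training genes nearest to the
#' query in embedding space act as templates, the i-th ranked template gets
#' weight `w_i = 1 - (r_i - 1) / K`, and each GO term is scored by the
#' weight-normalized frequency `sum(w_i I_i(term)) / sum(w_i)` over the
#' templates.
#'
#' @param model A `tnp_model`.
#' @param query_embedding One unit-norm embedding row (vector or 1-row
#'   matrix).
#' @param K Number of templates (default from the model config; capped at
#'   the training-set size).
#' @return Named numeric vector of confidences in \[0, 1\] over the model's
#'   label vocabulary.
#' @export
rank_score <- function(model, query_embedding, K = model$config$K) {
  if (K <= 0) stop("K must be positive")
  K <- min(as.integer(K), length(model$genes))
  q <- as.numeric(query_embedding)
  d <- as.numeric(.distance_matrix(matrix(q, 1L), model$train_embeddings))
  nearest <- order(d)[seq_len(K)]
  w <- 1 - (seq_len(K) - 1) / K
  drop(w %*% model$train_labels[nearest, , drop = FALSE]) / sum(w)
}

#' Predict GO term confidences from an expression profile
#'
#' Blends the two branches of the trained model: `w` times the
#' rank-transfer score from embedding neighbours plus `1 - w` times the
#' sigmoid output-layer score.  Apply [postprocess_scores()] to the result
#' before evaluation to enforce hierarchical consistency.
#'
#' @param model A `tnp_model`.
#' @param query Raw expression profile(s) over the training sample columns
#'   (vector or matrix with genes in rows).
#' @param w Blend weight in \[0, 1\] (default from the model config).
#' @return Named confidence vector for a single query, or a matrix with one
#'   row per query gene.
#' @export
predict_tnp <- function(model, query, w = model$config$w) {
  stopifnot(w >= 0, w <= 1)
  one <- is.null(dim(query))
  if (one) query <- matrix(query, nrow = 1L)
  xn <- apply_normalizer(model$normalizer, query)
  fwd <- .forward(model[c("W", "b", "Wo", "bo")], xn)
  st <- t(apply(fwd$un, 1L, function(u) rank_score(model, u)))
  s <- w * st + (1 - w) * fwd$scores
  colnames(s) <- model$label_vocab
  rownames(s) <- rownames(query)
  if (one) s[1L, ] else s
}
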