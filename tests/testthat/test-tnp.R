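test_that("normalizer z-scores per sample column and guards zero variance", {
  set.seed(10)
  x <- expression_matrix(cbind(rnorm(6), rep(3, 6), rnorm(6)),
                         paste0("g", 1:6), paste0("s", 1:3))
  expect_warning(st <- fit_normalizer(x, h = 2), "zero-variance")
  z <- sweep(sweep(unclass(x), 2, st$center), 2, st$scale, "/")
  expect_equal(unique(z[, 2]), 0)              # constant column -> zeros
})

test_that("full-rank PCA keeps all variance; truncation error equals the discarded eigenvalues", {
  set.seed(11)
  x <- expression_matrix(matrix(rnorm(50 * 20), 50),
                         paste0("g", 1:50), paste0("s", 1:20))
  st <- fit_normalizer(x, h = 20)
  expect_equal(sum(st$sdev[seq_len(st$h)]^2) / sum(st$sdev^2), 1)

  st5 <- fit_normalizer(x, h = 5)
  z <- sweep(sweep(unclass(x), 2, st5$center), 2, st5$scale, "/")
  proj <- apply_normalizer(st5, unclass(x)) %*% t(st5$rotation)
  resid <- sum((z - proj)^2)
  ev <- eigen(stats::cov(z), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(resid, (nrow(z) - 1) * sum(ev[-(1:5)]), tolerance = 1e-8)
})

test_that("applying the normalizer reproduces the fitted projection", {
  set.seed(12)
  x <- expression_matrix(matrix(rnorm(30 * 8), 30),
                         paste0("g", 1:30), paste0("s", 1:8))
  st <- fit_normalizer(x, h = 4)
  z <- sweep(sweep(unclass(x), 2, st$center), 2, st$scale, "/")
  fitted <- z %*% st$rotation
  expect_equal(apply_normalizer(st, unclass(x)[7, ]),
               fitted[7, , drop = FALSE], ignore_attr = TRUE)
  expect_equal(as.numeric(apply_normalizer(st, st$center)),
               rep(0, st$h))
  v <- rnorm(8)
  expect_equal(as.numeric(apply_normalizer(st, v)),
               as.numeric(((v - st$center) / st$scale) %*% st$rotation))
  expect_error(apply_normalizer(st, rnorm(5)), "samples")
})

test_that("normalized embedding distance lives on [0, 1] with antipodal maximum", {
  u <- c(1, 0, 0)
  expect_equal(pairwise_distance(u, u), 0)
  expect_equal(pairwise_distance(u, -u), 1)
  expect_error(pairwise_distance(u, c(2, 0, 0)), "unit-norm")
  set.seed(13)
  for (i in 1:50) {
    a <- rnorm(6); a <- a / sqrt(sum(a^2))
    b <- rnorm(6); b <- b / sqrt(sum(b^2))
    d <- pairwise_distance(a, b)
    expect_equal(d, (2 - 2 * sum(a * b)) / 4)
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("single-triplet loss hinges at the margin", {
  expect_equal(triplet_loss_single(0.3, 0.6, 0.2), 0)
  expect_equal(triplet_loss_single(0.5, 0.4, 0.2), 0.3)
  expect_equal(triplet_loss_single(0.4, 0.4, 1e-12), 0, tolerance = 1e-10)
})

test_that("batch-hard loss matches exhaustive enumeration and is permutation invariant", {
  set.seed(14)
  for (m in c(3, 5, 8)) {
    emb <- matrix(rnorm(m * 4), m)
    emb <- emb / sqrt(rowSums(emb^2))
    cls <- sample(1:2, m, replace = TRUE)
    same <- outer(cls, cls, "==")
    got <- suppressWarnings(batch_hard_loss(emb, same, 0.2))
    expect_equal(got, oracle_batch_hard(emb, same, 0.2))
    p <- sample(m)
    expect_equal(suppressWarnings(
      batch_hard_loss(emb[p, ], same[p, p], 0.2)), got)
  }
  # ideally separated batch: loss 0
  emb <- rbind(c(1, 0), c(1, 0), c(-1, 0), c(-1, 0))
  same <- outer(c(1, 1, 2, 2), c(1, 1, 2, 2), "==")
  expect_equal(batch_hard_loss(emb, same, 0.2), 0)
  # no contributing anchor
  expect_warning(z <- batch_hard_loss(emb, matrix(TRUE, 4, 4), 0.2),
                 "no anchor")
  expect_equal(z, 0)
})

test_that("hand-worked 3-gene batch: hardest positive/negative arithmetic", {
  emb <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  same <- rbind(c(TRUE, TRUE, FALSE),
                c(TRUE, TRUE, FALSE),
                c(FALSE, FALSE, TRUE))
  # d12 = 0.5, d13 = 1, d23 = 0.5; anchors 1 and 2 contribute, 3 has no pos
  want <- mean(c(max(0.5 + 0.2 - 1, 0), max(0.5 + 0.2 - 0.5, 0)))
  expect_equal(suppressWarnings(batch_hard_loss(emb, same, 0.2)), want)
})

test_that("cross-entropy loss matches the elementwise sum", {
  y <- matrix(c(1, 0, 0, 1, 1, 0), 2)
  expect_lte(cross_entropy_loss(y, y), 1e-5)
  expect_equal(cross_entropy_loss(matrix(0.5, 2, 3), y), log(2))
  set.seed(15)
  s <- matrix(runif(12, 0.05, 0.95), 4)
  yy <- matrix(rbinom(12, 1, 0.5), 4)
  brute <- 0
  for (i in 1:4) for (j in 1:3)
    brute <- brute - (yy[i, j] * log(s[i, j]) +
                        (1 - yy[i, j]) * log(1 - s[i, j]))
  expect_equal(cross_entropy_loss(s, yy), brute / 12)
  expect_error(cross_entropy_loss(s, yy[, 1:2]), "shapes")
})

test_that("training loss is triplet plus alpha times cross-entropy", {
  expect_equal(training_loss(0.4, 0.9, 0), 0.4)
  expect_equal(training_loss(0.2, 0.3, 1), 0.5)
  expect_equal(training_loss(0.4, 0.6, 0.5), 0.7)
})

test_that("analytic gradients agree with finite differences on a tiny net", {
  set.seed(16)
  m <- 6; h <- 3; r <- 2
  x <- matrix(rnorm(m * h), m)
  y <- matrix(rbinom(m * r, 1, 0.5), m)
  same <- outer(rep(1:2, each = 3), rep(1:2, each = 3), "==")
  params <- list(W = list(goblend:::.he_init(h, 4),
                          goblend:::.he_init(4, 3)),
                 b = list(rnorm(4), rnorm(3)),
                 Wo = goblend:::.he_init(3, r), bo = rnorm(r))
  loss_at <- function(p) {
    fwd <- goblend:::.forward(p, x)
    tri <- goblend:::.batch_hard_grad(fwd$un, same, 0.2)
    tri$loss + cross_entropy_loss(fwd$scores, y)
  }
  # analytic gradient of W1 via the same path train_tnp uses
  fwd <- goblend:::.forward(params, x)
  tri <- goblend:::.batch_hard_grad(fwd$un, same, 0.2)
  gun <- tri$grad
  g_dfcb <- (gun - fwd$un * rowSums(gun * fwd$un)) / fwd$norm
  gzo <- (fwd$scores - y) / length(y)
  g_dfcb <- g_dfcb + tcrossprod(gzo, params$Wo)
  gz2 <- g_dfcb * (fwd$z[[2]] > 0)
  ga1 <- tcrossprod(gz2, params$W[[2]])
  gz1 <- ga1 * (fwd$z[[1]] > 0)
  gW1 <- crossprod(x, gz1)
  eps <- 1e-6
  for (idx in sample(length(params$W[[1]]), 5)) {
    pp <- params; pp$W[[1]][idx] <- pp$W[[1]][idx] + eps
    pm <- params; pm$W[[1]][idx] <- pm$W[[1]][idx] - eps
    expect_equal(gW1[idx], (loss_at(pp) - loss_at(pm)) / (2 * eps),
                 tolerance = 1e-4)
  }
})

test_that("training is seed-reproducible and reduces the loss", {
  fx <- tiny_annotated()
  expr <- tiny_expression()
  cfg <- quick_tnp_config(seed = 9, epochs = 15)
  m1 <- train_tnp(expr, fx$annots, "MF", cfg)
  m2 <- train_tnp(expr, fx$annots, "MF", cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$W, m2$W)
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])
})

test_that("a single-function training set is rejected (no negatives)", {
  fx <- tiny_annotated()
  ann <- fx$ann; ann$go_id <- "a1"
  expect_error(
    train_tnp(tiny_expression(), annotation_db(ann, fx$dag), "MF",
              quick_tnp_config()),
    "no negatives")
})

test_that("embeddings are unit-norm, deterministic, and match hand arithmetic", {
  fx <- tiny_annotated()
  model <- train_tnp(tiny_expression(), fx$annots, "MF",
                     quick_tnp_config())
  e <- tnp_embed(model, unclass(tiny_expression())[c(1, 1, 5), ])
  expect_equal(unname(rowSums(e^2)), rep(1, 3), tolerance = 1e-6)
  expect_equal(e[1, ], e[2, ])

  # 2-unit toy network with hand-set weights
  toy <- list(W = list(matrix(c(1, 0, 0, -1), 2)), b = list(c(0, 1)),
              Wo = matrix(0, 2, 1), bo = 0)
  # input (2, 3): z = (2, -3) + (0, 1) = (2, -2); relu = (2, 0); unit (1, 0)
  expect_equal(as.numeric(tnp_embed(toy, matrix(c(2, 3), 1),
                                    normalized = TRUE)),
               c(1, 0))
})

test_that("rank transfer weights neighbours by 1 - (r - 1)/K", {
  fx <- tiny_annotated()
  model <- train_tnp(tiny_expression(), fx$annots, "MF",
                     quick_tnp_config())
  # K = 1 on a training gene's own embedding returns its indicator row
  s <- rank_score(model, model$train_embeddings[3, ], K = 1)
  expect_equal(unname(s), unname(model$train_labels[3, ]))
  expect_error(rank_score(model, model$train_embeddings[1, ], K = 0),
               "positive")
  # root term present in every training gene scores 1
  expect_equal(unname(rank_score(model, model$train_embeddings[1, ])["R"]),
               1)
  # hand-built model: 2 training genes, term only on the nearest
  hand <- list(train_embeddings = rbind(c(1, 0), c(0, 1)),
               train_labels = cbind(Q = c(1, 0), R = c(1, 1)),
               genes = c("t1", "t2"), config = list(K = 2))
  s <- rank_score(hand, c(1, 0), K = 2)
  expect_equal(unname(s["Q"]), 1 / 1.5)
  expect_equal(unname(s["R"]), 1)
})

test_that("prediction blends the rank and sigmoid branches convexly", {
  fx <- tiny_annotated()
  model <- train_tnp(tiny_expression(), fx$annots, "MF",
                     quick_tnp_config())
  q <- unclass(tiny_expression())[2, ]
  s1 <- predict_tnp(model, q, w = 1)
  s0 <- predict_tnp(model, q, w = 0)
  smid <- predict_tnp(model, q, w = 0.5)
  u <- tnp_embed(model, q)
  expect_equal(s1, rank_score(model, u[1, ]))
  fwd <- goblend:::.forward(model[c("W", "b", "Wo", "bo")],
                            apply_normalizer(model$normalizer, q))
  expect_equal(unname(s0), as.numeric(fwd$scores))
  expect_equal(smid, 0.5 * s1 + 0.5 * s0)
  expect_true(all(smid >= 0 & smid <= 1))
})
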