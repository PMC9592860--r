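test_that("positional encoding follows the even-sin/odd-cos convention", {
  pe0 <- positional_encoding(0, 8)
  expect_equal(pe0[seq(1, 8, by = 2)], rep(0, 4))  # sin 0
  expect_equal(pe0[seq(2, 8, by = 2)], rep(1, 4))  # cos 0
  pe1 <- positional_encoding(1, 4)
  expect_equal(pe1[1], sin(1), tolerance = 1e-12)
  expect_equal(pe1[1], 0.84147, tolerance = 1e-5)
  expect_equal(pe1[3], sin(1 / 10000^(2 / 4)), tolerance = 1e-12)
  for (pos in c(0, 1, 7, 100))
    expect_true(all(abs(positional_encoding(pos, 10)) <= 1))
})

test_that("scaled dot-product attention matches a scalar-loop oracle", {
  # QK' = 0: uniform attention averages the values
  Z <- matrix(0, 3, 2)
  V <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  expect_equal(unname(scaled_dot_attention(Z, Z, V)),
               matrix(colMeans(V), 3, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # single token: output is V itself
  expect_equal(as.vector(scaled_dot_attention(matrix(1:2, 1), matrix(3:4, 1),
                                              matrix(5:6, 1))),
               c(5, 6))
  # two-token hand case against an independent scalar-loop implementation
  Q <- K <- V2 <- diag(2)
  got <- scaled_dot_attention(Q, K, V2)
  oracle <- matrix(0, 2, 2)
  for (i in 1:2) {
    s <- numeric(2)
    for (j in 1:2) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(2)
    a <- exp(s) / sum(exp(s))
    for (d in 1:2) oracle[i, d] <- sum(a * V2[, d])
  }
  expect_equal(unname(got), oracle, tolerance = 1e-6, ignore_attr = TRUE)
  # every attention row is a probability distribution
  set.seed(1)
  A <- attr(scaled_dot_attention(matrix(rnorm(12), 4), matrix(rnorm(12), 4),
                                 matrix(rnorm(8), 4)), "weights")
  expect_equal(rowSums(A), rep(1, 4), tolerance = 1e-12)
  expect_true(all(A > 0))
  expect_error(scaled_dot_attention(matrix(0, 2, 3), matrix(0, 2, 2),
                                    matrix(0, 2, 2)), "width")
})

test_that("multi-head attention reduces to one head with identity projections", {
  set.seed(2)
  X <- matrix(rnorm(4 * 6), 4, 6)
  id <- list(Wq = diag(6), Wk = diag(6), Wv = diag(6), Wo = diag(6))
  expect_equal(multi_head_attention(X, id, n_heads = 1),
               unname(scaled_dot_attention(X, X, X)), ignore_attr = TRUE,
               tolerance = 1e-12)
  rnd <- list(Wq = matrix(rnorm(36), 6), Wk = matrix(rnorm(36), 6),
              Wv = matrix(rnorm(36), 6), Wo = matrix(rnorm(36), 6))
  out <- multi_head_attention(X, rnd, n_heads = 3)
  expect_equal(dim(out), dim(X))
  expect_error(multi_head_attention(X, rnd, n_heads = 4), "divisible")
})

test_that("feed-forward network matches its closed form", {
  p0 <- list(W1 = diag(3), b1 = rep(0, 3), W2 = diag(3), b2 = rep(0, 3))
  expect_equal(feed_forward(matrix(0, 2, 3), p0), matrix(0, 2, 3))
  # strongly negative inner bias forces the ReLU to zero -> output is b2
  pneg <- list(W1 = diag(3), b1 = rep(-100, 3), W2 = diag(3), b2 = 1:3)
  expect_equal(feed_forward(matrix(1, 2, 3), pneg),
               matrix(1:3, 2, 3, byrow = TRUE), ignore_attr = TRUE)
  # scalar hand case: max(0, 2*3 - 1) * 2 + 1 = 11
  ps <- list(W1 = matrix(3), b1 = -1, W2 = matrix(2), b2 = 1)
  expect_equal(as.vector(feed_forward(matrix(2), ps)), 11)
})

test_that("token embedding is a per-position linear lift plus encodings", {
  cfg <- model_config(3, 2, d_model = 4, n_heads = 2, conv_kernel = 3,
                      dropout = 0, seed = 1)
  params <- init_model_params(cfg)
  params$emb$bias[] <- 0
  PE <- do.call(rbind, lapply(0:2, positional_encoding, d_model = 4))
  expect_equal(embed_tokens(c(0, 0, 0), params, cfg), PE)
  x <- c(0.5, 2, 1)
  tok <- embed_tokens(x, params, cfg)
  expect_equal(dim(tok), c(3L, 4L))
  # doubling one scalar doubles its pre-positional token
  x2 <- x; x2[2] <- 2 * x[2]
  tok2 <- embed_tokens(x2, params, cfg)
  expect_equal(tok2[2, ] - PE[2, ], 2 * (tok[2, ] - PE[2, ]),
               tolerance = 1e-12)
  expect_equal(tok2[1, ], tok[1, ])
  expect_error(embed_tokens(c(1, 2), params, cfg), "expected 3")
})

test_that("encoder output shape responds to depth and decoder flag", {
  mk <- function(layers, dec)
    model_config(4, 3, d_model = 8, n_heads = 2, n_encoder_layers = layers,
                 use_decoder = dec, conv_channels = 2, conv_kernel = 3,
                 dropout = 0, seed = 9)
  cfg0 <- mk(0, FALSE)
  p0 <- init_model_params(cfg0)
  x <- c(1, 2, 0.5, 3)
  # zero-layer encoder without decoder passes the embedding through
  expect_equal(transformer_encode(x, p0, cfg0), embed_tokens(x, p0, cfg0))
  cfg1 <- mk(1, TRUE)
  p1 <- init_model_params(cfg1)
  expect_equal(nrow(transformer_encode(x, p1, cfg1)), 5L)
  cfg1b <- mk(1, FALSE)
  p1b <- init_model_params(cfg1b)
  expect_equal(nrow(transformer_encode(x, p1b, cfg1b)), 4L)
  # finite output across many random inputs
  set.seed(3)
  for (i in 1:100)
    expect_true(all(is.finite(transformer_encode(runif(4, 0, 5), p1,
                                                 cfg1))))
})

test_that("1-D convolution matches a direct-summation oracle", {
  cfg <- model_config(4, 2, d_model = 3, n_heads = 1, use_decoder = FALSE,
                      conv_channels = 2, conv_kernel = 3, dropout = 0,
                      seed = 1)
  set.seed(4)
  tokens <- matrix(rnorm(12), 4, 3)
  W <- matrix(rnorm(9 * 2), 9, 2)   # kernel 3 x 3 channels, 2 filters
  b <- c(0.1, -0.2)
  got <- conv_extract(tokens, list(W = W, b = b), cfg)
  expect_length(got, 4 * 2)
  padded <- rbind(0, tokens, 0)
  oracle <- numeric(8)
  for (t in 1:4) for (f in 1:2) {
    acc <- b[f]
    for (o in 1:3) for (ch in 1:3)
      acc <- acc + padded[t + o - 1, ch] * W[(o - 1) * 3 + ch, f]
    oracle[(t - 1) * 2 + f] <- max(0, acc)
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # a single filter picking out the centre of channel 1 returns its ReLU
  Wid <- matrix(0, 9, 1); Wid[3 + 1, 1] <- 1
  cfg1 <- model_config(4, 2, d_model = 3, n_heads = 1, use_decoder = FALSE,
                       conv_channels = 1, conv_kernel = 3, dropout = 0)
  expect_equal(conv_extract(tokens, list(W = Wid, b = 0), cfg1),
               pmax(0, tokens[, 1]))
})

test_that("softmax classifier and cross-entropy match closed forms", {
  p <- list(W = diag(2), b = c(0, 0))
  expect_equal(classify(c(0, 0), p), c(0.5, 0.5))
  expect_equal(classify(c(log(2), 0), p), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  # shift invariance
  expect_equal(classify(c(log(2) + 5, 5), p), c(2 / 3, 1 / 3),
               tolerance = 1e-12)
  probs <- softmax_rows(matrix(rnorm(12), 3, 4))
  expect_equal(rowSums(probs), rep(1, 3), tolerance = 1e-12)

  expect_equal(cross_entropy_loss(matrix(c(0, 1, 0), 1), 2L), 0)
  expect_equal(cross_entropy_loss(matrix(1 / 5, 2, 5), c(1L, 4L)), log(5),
               tolerance = 1e-12)
  two <- rbind(c(0.5, 0.5), c(0.25, 0.75))
  expect_equal(cross_entropy_loss(two, c(1L, 1L)), (log(2) + log(4)) / 2,
               tolerance = 1e-12)
  expect_equal(cross_entropy_loss(two, c(1L, 1L)), 1.0397, tolerance = 1e-4)
  expect_warning(cross_entropy_loss(rbind(c(0, 1)), 1L), "clamped")
})

test_that("batched forward pass reproduces the single-sequence primitives", {
  cfg <- model_config(3, 4, d_model = 8, n_heads = 2, n_encoder_layers = 2,
                      ffn_hidden = 12, use_decoder = TRUE,
                      conv_channels = 3, conv_kernel = 3, dropout = 0,
                      seed = 21)
  params <- random_params(cfg, seed = 22)
  set.seed(23)
  F_ <- matrix(runif(5 * 3, 0.2, 4), 5, 3)
  batch <- ldaformer:::nn_forward_batch(params, F_, cfg, train = FALSE)
  for (b in 1:5) {
    single <- model_forward(F_[b, ], params, cfg)
    expect_equal(unname(batch$probs[b, ]), unname(single),
                 tolerance = 1e-10)
  }
})

test_that("analytic gradients agree with finite differences", {
  configs <- list(
    model_config(3, 3, d_model = 8, n_heads = 2, ffn_hidden = 16,
                 use_decoder = TRUE, conv_channels = 4, conv_kernel = 3,
                 dropout = 0, seed = 42),
    model_config(4, 5, d_model = 12, n_heads = 3, n_encoder_layers = 2,
                 ffn_hidden = 20, use_decoder = FALSE, conv_channels = 3,
                 conv_kernel = 3, dropout = 0, seed = 7))
  flatten <- function(p, prefix = list()) {
    if (!is.list(p)) return(list(list(path = prefix, n = length(p))))
    idx <- if (!is.null(names(p)) && all(nzchar(names(p))))
      names(p) else seq_along(p)
    out <- list()
    for (i in idx) out <- c(out, flatten(p[[i]], c(prefix, list(i))))
    out
  }
  get_leaf <- function(p, path) { for (i in path) p <- p[[i]]; p }
  bump <- function(p, path, i, delta) {
    if (length(path) == 1) {
      p[[path[[1]]]][i] <- p[[path[[1]]]][i] + delta
    } else {
      p[[path[[1]]]] <- bump(p[[path[[1]]]], path[-1], i, delta)
    }
    p
  }
  for (cfg in configs) {
    params <- init_model_params(cfg)
    set.seed(99)
    F_ <- matrix(runif(3 * cfg$n_features, 0.5, 3), 3, cfg$n_features)
    y <- sample(cfg$n_classes, 3, replace = TRUE)
    fwd <- ldaformer:::nn_forward_batch(params, F_, cfg, train = FALSE)
    g <- ldaformer:::nn_backward_batch(params, fwd, y, cfg)
    loss_at <- function(p)
      ldaformer:::logit_loss(
        ldaformer:::nn_forward_batch(p, F_, cfg, FALSE)$logits, y)
    eps <- 1e-5
    for (leaf in flatten(params)) {
      gv <- get_leaf(g, leaf$path)
      for (i in sample(leaf$n, min(2, leaf$n))) {
        num <- (loss_at(bump(params, leaf$path, i, eps)) -
                  loss_at(bump(params, leaf$path, i, -eps))) / (2 * eps)
        rel <- abs(num - gv[i]) / max(1e-6, abs(num) + abs(gv[i]))
        expect_lt(rel, 1e-3,
                  label = paste0("rel grad err at ",
                                 paste(unlist(leaf$path), collapse = "/")))
      }
    }
  }
})
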