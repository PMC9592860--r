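# separable Gaussian classes in gene space, normalised flag set directly
gaussian_ld <- function(n_per = 30, k = 2, p = 10, sep = 6, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * p), k, p) * sep
  vals <- t(do.call(rbind, lapply(seq_len(k), function(c)
    sweep(matrix(rnorm(n_per * p, sd = 1), n_per, p), 2, centers[c, ],
          "+"))))
  em <- expression_matrix(vals, sprintf("g%d", seq_len(p)),
                          sprintf("c%d", seq_len(k * n_per)),
                          normalized = TRUE)
  labeled_dataset(em, rep(sprintf("t%d", seq_len(k)), each = n_per))
}

test_that("reduction dimension defaults to k - 1 and is bounded by it", {
  d5 <- gaussian_ld(k = 5, n_per = 20)
  proj <- fit_lda(d5)
  expect_equal(proj$d, 4L)
  expect_equal(ncol(proj$weights), 4L)
  expect_equal(fit_lda(gaussian_ld(k = 2))$d, 1L)
  expect_error(fit_lda(d5, d = 5), "1..k-1")
  expect_error(fit_lda(d5, d = 0), "1..k-1")
  raw <- labeled_dataset(tiny_em(matrix(rpois(40, 2), 4, 10)),
                         rep(c("a", "b"), 5))
  expect_error(fit_lda(raw), "normalis")
})

test_that("shifted training projection is strictly positive and consistent", {
  data <- gaussian_ld(k = 3, n_per = 25, seed = 2)
  proj <- fit_lda(data)
  feats <- predict(proj, data$matrix)
  expect_true(min(feats) > 0)
  expect_equal(dim(feats), c(75L, 2L))
  # transform equals the explicit matrix product plus shift
  oracle <- t(data$matrix$values) %*% proj$weights + proj$shift
  expect_equal(unname(feats), unname(oracle), tolerance = 1e-12)
  # duplicated cell gives identical rows
  dup <- expression_matrix(cbind(data$matrix$values,
                                 data$matrix$values[, 1]),
                           data$matrix$gene_symbols,
                           c(data$matrix$cell_ids, "copy"),
                           normalized = TRUE)
  fd <- suppressWarnings(predict(proj, dup))
  expect_equal(fd["copy", ], fd[1, ])
})

test_that("a separable two-class problem projects with zero range overlap", {
  data <- gaussian_ld(k = 2, n_per = 30, sep = 8, seed = 3)
  proj <- fit_lda(data)
  feats <- predict(proj, data$matrix)
  r1 <- range(feats[data$labels == 1, 1])
  r2 <- range(feats[data$labels == 2, 1])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])
})

test_that("nearest-centroid on the k-1 reduction recovers separable classes", {
  data <- gaussian_ld(k = 4, n_per = 40, p = 20, sep = 5, seed = 4)
  proj <- fit_lda(data)
  feats <- predict(proj, data$matrix)
  centroids <- do.call(rbind, lapply(1:4, function(c)
    colMeans(feats[data$labels == c, , drop = FALSE])))
  pred <- apply(feats, 1, function(x)
    which.min(colSums((t(centroids) - x)^2)))
  expect_gte(mean(pred == data$labels), 0.95)
})

test_that("projection errors on an incompatible gene list", {
  data <- gaussian_ld(k = 2, seed = 5)
  proj <- fit_lda(data)
  wrong <- expression_matrix(data$matrix$values[1:5, ],
                             sprintf("other%d", 1:5),
                             data$matrix$cell_ids, normalized = TRUE)
  expect_error(predict(proj, wrong), "missing")
  # reordered genes are matched back by symbol
  perm <- sample(n_genes(data$matrix))
  reord <- expression_matrix(data$matrix$values[perm, ],
                             data$matrix$gene_symbols[perm],
                             data$matrix$cell_ids, normalized = TRUE)
  expect_equal(predict(proj, reord), predict(proj, data$matrix))
})

test_that("discriminant direction agrees with an independent LDA solver", {
  skip_if_not_installed("MASS")
  # well-conditioned two-class problem (n >> p) where shrinkage is inert
  data <- gaussian_ld(k = 2, n_per = 100, p = 5, sep = 2, seed = 6)
  proj <- fit_lda(data, shrinkage = 1e-9)
  ours <- predict(proj, data$matrix)[, 1]
  ref <- MASS::lda(t(data$matrix$values),
                   grouping = factor(data$labels))
  theirs <- as.vector(t(data$matrix$values) %*% ref$scaling)
  expect_gt(abs(stats::cor(ours, theirs)), 0.999)
})
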