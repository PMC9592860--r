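test_that("gene-symbol cleaning drops duplicates and off-reference genes", {
  em <- tiny_em(matrix(1:8, 4, 2), genes = c("A", "B", "B", "C"))
  cleaned <- clean_gene_symbols(em)
  expect_identical(cleaned$gene_symbols, c("A", "C"))
  expect_identical(cleaned$values, em$values[c(1, 4), , drop = FALSE])

  unique_em <- tiny_em(matrix(1:6, 3, 2), genes = c("A", "B", "C"))
  expect_identical(clean_gene_symbols(unique_em)$values, unique_em$values)

  ref <- clean_gene_symbols(tiny_em(matrix(1:4, 2, 2),
                                    genes = c("A", "B")),
                            reference_symbols = "A")
  expect_identical(ref$gene_symbols, "A")

  expect_error(clean_gene_symbols(tiny_em(matrix(1:4, 2, 2),
                                          genes = c("X", "X"))),
               "every gene")
})

test_that("log-normalisation follows the global-scaling convention", {
  em <- tiny_em(cbind(c(1, 1, 1, 1), c(0, 0, 0, 0), c(2, 0, 6, 0)))
  nm <- log_normalize(em, scale_factor = 1e4)
  expect_true(nm$normalized)
  # column of equal counts: each entry log(1 + scale/4)
  expect_equal(nm$values[, 1], rep(log(1 + 2500), 4), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(unname(nm$values[1, 1]), 7.8244, tolerance = 1e-4)
  # all-zero cells stay all-zero
  expect_equal(unname(nm$values[, 2]), rep(0, 4))
  # scaling one cell's raw counts leaves its normalised column unchanged
  em2 <- tiny_em(cbind(c(1, 1, 1, 1) * 7, c(0, 0, 0, 0), c(2, 0, 6, 0)))
  expect_equal(log_normalize(em2)$values[, 1], nm$values[, 1])
  # round trip: expm1 of a nonzero column sums back to the scale factor
  inv <- expm1(nm$values[, 3])
  expect_equal(sum(inv), 1e4, tolerance = 1e-8)
  expect_error(log_normalize(tiny_em(matrix(c(-1, 2), 1, 2))),
               "non-negative")
  expect_error(log_normalize(nm), "already")
})

test_that("rare-type filtering uses a strict threshold and is idempotent", {
  n <- 1000
  labels <- c(rep("big", n - 10), rep("tiny", 4), rep("edge", 6))
  em <- tiny_em(matrix(rpois(2 * n, 2), 2, n))
  data <- labeled_dataset(em, labels)
  filt <- filter_rare_cell_types(data, min_fraction = 0.005)
  # threshold is 5 cells: 4 < 5 dropped, 6 >= 5 kept
  expect_setequal(filt$class_names, c("big", "edge"))
  expect_equal(n_cells(filt$matrix), n - 4)
  # dense re-indexing and preserved cell order
  expect_true(all(filt$labels %in% seq_along(filt$class_names)))
  expect_identical(filt$matrix$cell_ids,
                   setdiff(data$matrix$cell_ids,
                           data$matrix$cell_ids[labels == "tiny"]))
  # idempotent; min_fraction 0 is the identity
  again <- filter_rare_cell_types(filt, 0.005)
  expect_identical(again$labels, filt$labels)
  expect_identical(filter_rare_cell_types(data, 0)$labels, data$labels)
  only <- labeled_dataset(em, c(rep("a", 995), rep("b", 5)))
  expect_error(filter_rare_cell_types(only, 0.99), "fewer than 2")
})

test_that("zero-gene removal treats a dataset pair jointly", {
  a <- tiny_em(rbind(c(0, 0), c(1, 2), c(0, 0)),
               genes = c("g1", "g2", "g3"))
  b <- tiny_em(rbind(c(3, 0), c(0, 0), c(0, 0)),
               genes = c("g1", "g2", "g3"), cells = c("x1", "x2"))
  pair <- remove_zero_genes(a, b)
  # g1 zero in a but expressed in b -> kept; g3 zero in both -> dropped
  expect_identical(pair$a$gene_symbols, c("g1", "g2"))
  expect_identical(pair$a$gene_symbols, pair$b$gene_symbols)
  single <- remove_zero_genes(a)
  expect_identical(single$gene_symbols, "g2")
  full <- tiny_em(matrix(1:4, 2, 2))
  expect_identical(remove_zero_genes(full)$values, full$values)
  other <- tiny_em(matrix(1:4, 2, 2), genes = c("zz1", "zz2"))
  expect_error(remove_zero_genes(full, other), "intersect")
})

test_that("cross-dataset harmonisation intersects types and drops shared cells", {
  mk <- function(labels, prefix) {
    n <- length(labels)
    labeled_dataset(tiny_em(matrix(rpois(3 * n, 3), 3, n),
                            cells = sprintf("%s%d", prefix, seq_len(n))),
                    labels)
  }
  train <- mk(c("T", "T", "B", "NK"), "tr")
  test <- mk(c("T", "B", "DC", "DC"), "te")
  h <- harmonize_pair(train, test)
  expect_identical(h$train$class_names, h$test$class_names)
  expect_setequal(h$train$class_names, c("B", "T"))
  expect_true(all(!h$test$matrix$cell_ids %in% h$train$matrix$cell_ids))

  same <- mk(c("T", "T", "B", "B"), "s")
  expect_error(harmonize_pair(same, same), "every test cell")
  expect_error(harmonize_pair(mk(c("T", "T"), "a"), mk(c("DC", "DC"), "b")),
               "no cell types")
})

test_that("train/test splitting is stratified, exact and reproducible", {
  data <- labeled_dataset(tiny_em(matrix(rpois(200, 1), 2, 100)),
                          rep(c("a", "b"), each = 50))
  sp <- split_train_test(data, 0.8, seed = 5)
  expect_equal(n_cells(sp$train$matrix), 80)
  expect_equal(n_cells(sp$test$matrix), 20)
  expect_identical(sort(c(sp$train$matrix$cell_ids,
                          sp$test$matrix$cell_ids)),
                   sort(data$matrix$cell_ids))
  expect_length(intersect(sp$train$matrix$cell_ids,
                          sp$test$matrix$cell_ids), 0)
  expect_identical(sp$train$class_names, sp$test$class_names)
  # per-class train counts within 1 of 0.8 * class size
  per_class <- table(sp$train$labels)
  expect_true(all(abs(per_class - 40) <= 1))
  # identical seeds agree bit for bit; different seeds differ
  sp2 <- split_train_test(data, 0.8, seed = 5)
  expect_identical(sp$train$matrix$cell_ids, sp2$train$matrix$cell_ids)
  sp3 <- split_train_test(data, 0.8, seed = 6)
  expect_false(identical(sp$train$matrix$cell_ids,
                         sp3$train$matrix$cell_ids))
  # unstratifiable class is named in the error
  bad <- labeled_dataset(tiny_em(matrix(rpois(20, 1), 2, 10)),
                         c(rep("big", 9), "lonely"))
  expect_error(split_train_test(bad), "lonely")
})
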