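test_that("abundance tables validate ids and coordinates", {
  v <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  tab <- abundance_table(v)
  expect_s3_class(tab, "marr_abundance")
  expect_identical(tab$layers, "replicate")
  bad <- v; rownames(bad) <- c("a", "a")
  expect_error(abundance_table(bad), "duplicate feature")
  meta <- data.frame(sample_id = c("s1", "s2"), grp = c("g1", "g1"))
  expect_error(abundance_table(v, meta), "missing from metadata: s3")
  meta3 <- data.frame(sample_id = c("s1", "s2", "s3"),
                      grp = c("g1", "g1", "g1"))
  expect_error(abundance_table(v, meta3), "not unique")
})

test_that("pair enumeration yields all within-group combinations", {
  # single layer, I = 3 -> C(3,2) = 3 pairs
  tab1 <- toy_table(5, c(rep = 3))
  expect_identical(nrow(enumerate_pairs(tab1)), 3L)

  # subject x technical-replicate design: 131 * C(3,2) = 393 pairs
  ids <- as.vector(outer(sprintf("subj%03d", 1:131), paste0("_r", 1:3),
                         paste0))
  v <- matrix(1, 2, length(ids),
              dimnames = list(c("f1", "f2"), ids))
  meta <- data.frame(sample_id = ids,
                     subject = rep(sprintf("subj%03d", 1:131), each = 3),
                     replicate = rep(paste0("r", 1:3), 131))
  pairs <- enumerate_pairs(abundance_table(v, meta), "replicate")
  expect_identical(nrow(pairs), 393L)
  expect_identical(length(unique(pairs$group)), 131L)

  # single biological layer with I = 1130 -> C(1130, 2) pairs
  ids <- sprintf("s%04d", 1:1130)
  v <- matrix(1, 1, 1130, dimnames = list("f1", ids))
  expect_equal(nrow(enumerate_pairs(abundance_table(v))),
               choose(1130L, 2L))

  # arbitrary unbalanced groups: total must equal sum of C(n,2)
  sizes <- c(2, 5, 3, 4)
  ids <- unlist(lapply(seq_along(sizes), function(g) {
    paste0("g", g, "_r", seq_len(sizes[g]))
  }))
  meta <- data.frame(sample_id = ids,
                     grp = rep(paste0("g", seq_along(sizes)), sizes),
                     rep = unlist(lapply(sizes, function(n) paste0("r", 1:n))))
  v <- matrix(1, 1, length(ids), dimnames = list("f1", ids))
  expect_equal(nrow(enumerate_pairs(abundance_table(v, meta), "rep")),
               sum(choose(sizes, 2)))
})

test_that("pairing errors guide the user to pooling", {
  tab <- toy_table(4, c(op = 2, rep = 3))
  expect_error(enumerate_pairs(tab, "op"), "pool")
  ids <- c("g1_r1", "g1_r2", "g2_r1")
  meta <- data.frame(sample_id = ids, grp = c("g1", "g1", "g2"),
                     rep = c("r1", "r2", "r1"))
  v <- matrix(1, 1, 3, dimnames = list("f1", ids))
  expect_error(enumerate_pairs(abundance_table(v, meta), "rep"),
               "single replicate")
})

test_that("pooling sums abundances beneath the target layer", {
  # two replicates with values 1 and 2 pool to 3
  v <- matrix(c(1, 2), 1, 2, dimnames = list("f1", c("a_r1", "a_r2")))
  meta <- data.frame(sample_id = c("a_r1", "a_r2"), grp = c("a", "a"),
                     rep = c("r1", "r2"))
  pooled <- pool_lower_layers(abundance_table(v, meta), "grp")
  expect_equal(unname(pooled$values[1, 1]), 3)
  expect_identical(pooled$layers, "grp")

  # pooling at the bottom layer is the identity on values
  tab <- toy_table(6, c(op = 2, rep = 2))
  same <- pool_lower_layers(tab, "rep")
  expect_equal(unname(sort(colSums(same$values))),
               unname(sort(colSums(tab$values))))

  # 3 x 3 x 3 design: sums match brute-force aggregation at both layers
  tab <- toy_table(10, c(op = 3, spike = 3, rep = 3), seed = 42)
  mid <- pool_lower_layers(tab, "spike")
  expect_identical(ncol(mid$values), 9L)
  top <- pool_lower_layers(tab, "op")
  expect_identical(ncol(top$values), 3L)
  co <- tab$coordinates
  for (s in colnames(mid$values)) {
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    idx <- co$op == parts[1] & co$spike == parts[2]
    expect_equal(mid$values[, s],
                 rowSums(tab$values[, co$sample_id[idx], drop = FALSE]))
  }
  # conservation: pooled totals equal the grand totals per feature
  expect_equal(rowSums(mid$values), rowSums(tab$values))
  expect_equal(rowSums(top$values), rowSums(tab$values))
})

test_that("pooling refuses missing values", {
  tab <- toy_table(4, c(op = 2, rep = 2))
  tab$values[1, 1] <- NA
  expect_error(pool_lower_layers(tab, "op"), "impute")
})
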