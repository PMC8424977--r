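test_that("missingness filter keeps features at the boundary", {
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:10)))
  # plant missing fractions 0, .1, .2, .3, .5
  v[2, 1] <- NA
  v[3, 1:2] <- NA
  v[4, 1:3] <- NA
  v[5, 1:5] <- NA
  out <- suppressMessages(filter_missing(v, 0.2))
  expect_identical(rownames(out), c("f1", "f2", "f3"))
  expect_identical(attr(out, "removed_features"), c("f4", "f5"))
  expect_error(suppressMessages(filter_missing(v[5, , drop = FALSE], 0.2)),
               "all features")
})

test_that("kNN imputation averages the nearest feature profiles", {
  # no missing values -> identity
  v <- matrix(rnorm(30), 3, 10,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:10)))
  expect_equal(impute_knn(v, k = 2), v)

  # k = 1: nearest neighbour identical elsewhere donates its value
  v <- rbind(f1 = c(1, 2, NA, 4, 5),
             f2 = c(1, 2, 7, 4, 5),
             f3 = c(50, 60, 70, 80, 90))
  colnames(v) <- paste0("s", 1:5)
  out <- impute_knn(v, k = 1)
  expect_equal(out["f1", "s3"], 7)

  # postcondition: never any missing cells left
  set.seed(8)
  v <- matrix(rnorm(200), 20, 10,
              dimnames = list(paste0("f", 1:20), paste0("s", 1:10)))
  v[sample(length(v), 30)] <- NA
  out <- impute_knn(v, k = 5)
  expect_false(anyNA(out))
  # observed cells are untouched
  expect_equal(out[!is.na(v)], v[!is.na(v)])

  v_all_na <- rbind(f1 = rep(NA_real_, 4), f2 = rnorm(4))
  colnames(v_all_na) <- paste0("s", 1:4)
  expect_error(impute_knn(v_all_na), "no observed values")
})

test_that("quantile normalization equalizes sample distributions", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6))
  rownames(v) <- paste0("f", 1:3)
  out <- normalize_quantile(v)
  expect_equal(unname(out[, "s1"]), c(1.5, 3, 4.5))
  expect_equal(unname(out[, "s2"]), c(1.5, 3, 4.5))

  # identical samples are unchanged
  v <- matrix(rep(c(5, 1, 3), 4), 3, 4,
              dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  expect_equal(normalize_quantile(v), v)

  # permuted samples end up sharing the same sorted values
  set.seed(2)
  a <- rnorm(20)
  v <- cbind(s1 = a, s2 = sample(a))
  rownames(v) <- paste0("f", 1:20)
  out <- normalize_quantile(v)
  expect_equal(unname(sort(out[, 1])), unname(sort(out[, 2])))
  expect_error(normalize_quantile(cbind(s1 = c(1, NA))), "impute")
})

test_that("median normalization aligns every sample median", {
  v <- cbind(s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(10, 20, 30))
  rownames(v) <- paste0("f", 1:3)
  out <- normalize_median(v)
  grand <- median(v)
  expect_equal(unname(apply(out, 2, median)), rep(grand, 3))
  set.seed(4)
  v <- matrix(rexp(60) + 0.1, 6, 10,
              dimnames = list(paste0("f", 1:6), paste0("s", 1:10)))
  out <- normalize_median(v)
  meds <- apply(out, 2, median)
  expect_equal(unname(meds), rep(median(v), 10))
})

test_that("run-day normalization rescales within days per metabolite", {
  # day-A median 2, day-B median 4, overall median 3
  v <- rbind(f1 = c(1, 2, 3, 3, 4, 5))
  colnames(v) <- paste0("s", 1:6)
  day <- c("A", "A", "A", "B", "B", "B")
  out <- normalize_runday(v, day)
  expect_equal(unname(out[1, 1:3]), c(1, 2, 3) * 3 / 2)
  expect_equal(unname(out[1, 4:6]), c(3, 4, 5) * 3 / 4)

  # single run day -> identity; constant metabolite -> unchanged
  v <- rbind(f1 = c(2, 3, 4), f2 = c(7, 7, 7))
  colnames(v) <- paste0("s", 1:3)
  expect_equal(normalize_runday(v, rep("d1", 3)), v)
  out <- normalize_runday(v, c("d1", "d1", "d2"))
  expect_equal(unname(out["f2", ]), rep(7, 3))
})

test_that("outlier samples are removed by aggregate median z-score", {
  set.seed(5)
  v <- matrix(rnorm(100, 10), 10, 10,
              dimnames = list(paste0("f", 1:10), paste0("s", 1:10)))
  out <- remove_outlier_samples(v)
  expect_identical(ncol(out), 10L)
  v[, 4] <- v[, 4] * 100
  out <- suppressMessages(remove_outlier_samples(v, 2.5))
  expect_identical(attr(out, "removed_samples"), "s4")
  expect_identical(ncol(remove_outlier_samples(v, Inf)), 10L)
})

test_that("log transform is exact and reports offending cells", {
  v <- cbind(s1 = c(1, 8), s2 = c(2, 16))
  rownames(v) <- c("f1", "f2")
  out <- log_transform(v)
  expect_equal(unname(out["f1", "s1"]), 0)
  expect_equal(unname(out["f2", "s1"]), 3)
  expect_equal(2^out, v)
  v["f2", "s2"] <- -1
  expect_error(log_transform(v), "'f2', sample 's2'")
})

test_that("quantile normalization leaves MaRR pair calls unchanged", {
  set.seed(12)
  v <- matrix(2^rnorm(400, 8), 200, 2,
              dimnames = list(sprintf("f%03d", 1:200), c("s1", "s2")))
  raw <- marr_pair(v[, 1], v[, 2], alpha = 0.05, tie_seed = 9)
  nq <- normalize_quantile(v)
  norm <- marr_pair(nq[, 1], nq[, 2], alpha = 0.05, tie_seed = 9)
  expect_identical(raw$calls, norm$calls)
  expect_identical(raw$k_hat, norm$k_hat)
})
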