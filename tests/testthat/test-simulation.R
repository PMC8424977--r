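test_that("bivariate-normal draws match their design parameters", {
  sim <- simulate_bivariate_normal(2860, pi1 = 0.9, mu_r = 4.13,
                                   rho_r = 0.99, seed = 1)
  expect_identical(sum(sim$reproducible), 2574L)   # round(0.9 * 2860)
  expect_identical(length(sim$t1), 2860L)

  # sample correlation of reproducible pairs within 3 SE of rho_r
  sim <- simulate_bivariate_normal(2860, pi1 = 0.9, mu_r = 4.01,
                                   rho_r = 0.45, seed = 2)
  r <- cor(sim$t1[sim$reproducible], sim$t2[sim$reproducible])
  se <- (1 - 0.45^2) / sqrt(sum(sim$reproducible))
  expect_lt(abs(r - 0.45), 3 * se)

  # independence limit
  sim0 <- simulate_bivariate_normal(4000, pi1 = 0.5, mu_r = 4, rho_r = 0,
                                    seed = 3)
  r0 <- cor(sim0$t1[sim0$reproducible], sim0$t2[sim0$reproducible])
  expect_lt(abs(r0), 3 / sqrt(2000))
})

test_that("rank-dependent correlation follows the linear map in t1", {
  sim <- simulate_rank_correlated(40000, pi1 = 0.5, r0 = 0.4, seed = 4)
  t1 <- sim$t1[sim$reproducible]
  t2 <- sim$t2[sim$reproducible]
  resid <- t2 - t1
  # conditional variance is 1 - r^2 with r = (1 - r0)(t1 - 4) + r0;
  # check it inside narrow t1 bins, including both endpoints
  for (lo in c(4, 4.45, 4.9)) {
    idx <- t1 >= lo & t1 < lo + 0.1
    r_mid <- (1 - 0.4) * (lo + 0.05 - 4) + 0.4
    expect_lt(abs(var(resid[idx]) - (1 - r_mid^2)), 0.05)
  }
  # near-perfect correlation at the top of the range
  top <- t1 > 4.99
  expect_lt(max(abs(resid[top])), 0.5)

  simp <- simulate_rank_correlated(2000, pi1 = 0.5, r0 = 0.99, seed = 5)
  expect_lt(sd(simp$t2[simp$reproducible] - simp$t1[simp$reproducible]),
            0.2)
})

test_that("heavy-tailed noise differs from the normal design only in tails", {
  simn <- simulate_bivariate_normal(20000, pi1 = 0.3, mu_r = 4.01,
                                    rho_r = 0.99, seed = 6)
  simt <- simulate_heavy_tailed(20000, pi1 = 0.3, mu_r = 4.01,
                                rho_r = 0.99, seed = 6)
  expect_identical(simt$reproducible, simn$reproducible)
  kurt <- function(x) mean((x - mean(x))^4) / var(x)^2
  irr_n <- simn$t1[!simn$reproducible]
  irr_t <- simt$t1[!simt$reproducible]
  expect_gt(kurt(irr_t), kurt(irr_n) + 1)
  # labels partition the rows
  expect_identical(sum(simt$reproducible) + sum(!simt$reproducible),
                   20000L)
})

test_that("ideal split plants identical top ranks", {
  sim <- simulate_ideal(100, pi1 = 0.4, seed = 7)
  expect_identical(sim$ranks_a[sim$reproducible],
                   sim$ranks_b[sim$reproducible])
  expect_true(all(sim$ranks_a[sim$reproducible] <= 40L))
  expect_true(all(sim$ranks_a[!sim$reproducible] > 40L))
  expect_identical(sort(sim$ranks_a), 1:100)
  expect_identical(sort(sim$ranks_b), 1:100)
})

test_that("confusion scoring follows the rejection conventions", {
  perfect <- score_calls(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(perfect$fdr, 0)
  expect_equal(perfect$ndr, 0)
  expect_equal(perfect$power, 1)

  # 2 false and 8 true rejections -> FDR 0.2
  calls <- rep(c(1, 0), c(10, 10))
  truth <- rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 2, 8))
  sc <- score_calls(calls, truth)
  expect_equal(sc$fp, 2L); expect_equal(sc$tp, 8L); expect_equal(sc$q, 10L)
  expect_equal(sc$fdr, 0.2)
  expect_equal(sc$ndr, 0.2)
  expect_equal(sc$tn + sc$fp + sc$fn + sc$tp, 20L)

  none <- score_calls(rep(0, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(none$fdr, 0)
  expect_equal(none$power, 0)
  expect_error(score_calls(1:3, c(TRUE, FALSE)), "length")
})

test_that("simulation studies are reproducible and behave sensibly", {
  grid <- data.frame(sim = c("bvnormal", "rankcor"),
                     mu_r = c(4.01, NA), rho_r = c(0.99, NA),
                     r0 = c(NA, 0.6), pi1 = c(0.75, 0.75))
  a <- run_study(grid, n_datasets = 4, m = 400, master_seed = 77)
  b <- run_study(grid, n_datasets = 4, m = 400, master_seed = 77)
  expect_identical(a, b)
  c <- run_study(grid, n_datasets = 4, m = 400, master_seed = 78)
  expect_false(identical(a$mean_fdr, c$mean_fdr))
  expect_true(all(a$mean_power > 0.8))
  expect_true(all(a$mean_fdr >= 0 & a$mean_fdr <= 1))
})

test_that("RSD is the percent coefficient of variation", {
  expect_equal(rsd(c(2, 2, 2)), 0)
  expect_equal(rsd(c(8, 10, 12)), 20)          # mean 10, sample sd 2
  v <- rexp(20) + 1
  expect_equal(rsd(3.7 * v), rsd(v))           # scale invariance
  expect_equal(rsd(c(-8, -10, -12)), 20)       # absolute mean
  expect_error(rsd(c(-1, 1)), "zero mean")
  expect_error(rsd(5), "at least 2")
})

test_that("the RSD cutoff fails to remove low-variance irreproducible noise", {
  # technical-replicate style data: reproducible features share a latent
  # level across samples, irreproducible features are independent
  # low-variance noise; RSD sees only within-feature spread and keeps
  # the noise features, while MaRR separates the two classes
  set.seed(30)
  n1 <- 150; n0 <- 50; ns <- 6
  latent <- rnorm(n1, 4.01, 0.17 * sqrt(0.99))
  repro <- 2^(latent + matrix(rnorm(n1 * ns, 0, 0.17 * sqrt(0.01)), n1, ns))
  irrep <- 2^matrix(rnorm(n0 * ns, 3.2, 0.05), n0, ns)
  v <- rbind(repro, irrep)
  dimnames(v) <- list(sprintf("f%03d", 1:(n1 + n0)), paste0("s", 1:ns))
  truth <- rep(c(1L, 0L), c(n1, n0))

  res <- marr_layer(abundance_table(v), alpha = 0.05, master_seed = 3)
  flags <- metabolite_reproducibility(res$matrix, 0.5)
  cmp <- rsd_comparison(v, flags, rsd_cutoff = 25)
  expect_equal(nrow(cmp$table), n1 + n0)
  # all truly irreproducible features have small RSD and pass the filter
  expect_equal(cmp$removed_irreproducible +
                 cmp$retained_irreproducible, sum(flags == 0))
  expect_gt(cmp$retained_irreproducible / max(1, sum(flags == 0)), 0.9)
  # MaRR itself separates the classes well on the same data
  sc <- score_calls(flags, truth)
  expect_gt(sc$power, 0.9)
  expect_lt(sc$fdr, 0.2)
  # zero-RSD features are never removed at a positive cutoff
  const <- matrix(5, 3, 4, dimnames = list(paste0("c", 1:3),
                                           paste0("s", 1:4)))
  cc <- rsd_comparison(const, c(1, 0, 1), rsd_cutoff = 25)
  expect_identical(cc$removed_irreproducible + cc$removed_reproducible, 0L)
})
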