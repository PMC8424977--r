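# Simulation generators with known reproducibility truth, scoring of
# MaRR calls against that truth, and the RSD baseline.

#' Ideal perfect-split rank data
#'
#' Generates rank pairs under the ideal setting: the reproducible
#' metabolites occupy the top ranks `1..k` identically in both
#' replicates (perfect correlation of highly ranked signals), while the
#' irreproducible metabolites receive two independent uniform
#' permutations of the remaining ranks `k+1..M`.
#'
#' @param m Number of metabolites M.
#' @param pi1 True proportion of reproducible signals in (0, 1);
#'   `k = round(pi1 * m)`.
#' @param seed Optional integer seed.
#' @return List with `ranks_a`, `ranks_b`, `reproducible` (logical
#'   truth), `pi1`, `m`.
#' @export
simulate_ideal <- function(m, pi1, seed = NULL) {
  k <- round(pi1 * m)
  stopifnot(k >= 1L, k < m)
  with_seed(seed, {
    top <- sample.int(k)
    ra <- c(top, k + sample.int(m - k))
    rb <- c(top, k + sample.int(m - k))
    list(ranks_a = as.integer(ra), ranks_b = as.integer(rb),
         reproducible = c(rep(TRUE, k), rep(FALSE, m - k)),
         pi1 = pi1, m = m)
  })
}

#' Bivariate-normal replicate statistics (constant correlation)
#'
#' The reproducible metabolites are drawn as bivariate normal pairs with
#' common mean `mu_r`, standard deviation `sigma_r` and correlation
#' `rho_r`; the irreproducible metabolites are independent normal pairs
#' at a lower mean `mu_ir` with standard deviation `sigma_ir`. Defaults
#' follow summary statistics of processed untargeted LC-MS plasma data:
#' reproducible abundances around 3.9-4.1 on the log scale with sd 0.17,
#' irreproducible around 3.2 with sd 0.05.
#'
#' @param m Number of metabolites, default 2860.
#' @param pi1 True proportion of reproducible signals;
#'   `round(pi1 * m)` rows are reproducible.
#' @param mu_r Mean of reproducible abundances (e.g. 3.89, 4.01, 4.13).
#' @param rho_r Correlation of reproducible pairs (e.g. 0.45, 0.99).
#' @param mu_ir,sigma_r,sigma_ir Remaining distribution parameters.
#' @param seed Optional integer seed.
#' @return List with `t1`, `t2` (replicate statistics), `reproducible`
#'   (logical truth), `pi1`, `m`.
#' @export
simulate_bivariate_normal <- function(m = 2860L, pi1, mu_r, rho_r,
                                      mu_ir = 3.2, sigma_r = 0.17,
                                      sigma_ir = 0.05, seed = NULL) {
  stopifnot(pi1 > 0, pi1 < 1, sigma_r > 0, sigma_ir > 0, abs(rho_r) <= 1)
  n1 <- round(pi1 * m)
  n0 <- m - n1
  with_seed(seed, {
    sigma <- sigma_r^2 * matrix(c(1, rho_r, rho_r, 1), 2L)
    rep_pairs <- MASS::mvrnorm(n1, mu = c(mu_r, mu_r), Sigma = sigma)
    t1 <- c(rep_pairs[, 1L], stats::rnorm(n0, mu_ir, sigma_ir))
    t2 <- c(rep_pairs[, 2L], stats::rnorm(n0, mu_ir, sigma_ir))
    list(t1 = t1, t2 = t2,
         reproducible = c(rep(TRUE, n1), rep(FALSE, n0)),
         pi1 = pi1, m = m)
  })
}

#' Replicate statistics with rank-dependent correlation
#'
#' The reproducible metabolites have a first statistic
#' `t1 ~ Uniform(4, 5)` and a second statistic drawn conditionally as
#' `t2 | t1 ~ Normal(t1, 1 - r^2)` with a correlation that increases
#' linearly with the signal: `r = (1 - r0) * (t1 - 4) + r0`, so the
#' lowest-ranked reproducible signals have correlation `r0` and the
#' highest have perfect correlation. Irreproducible metabolites are
#' independent normal pairs as in [simulate_bivariate_normal()].
#'
#' @param m Number of metabolites, default 2860.
#' @param pi1 True proportion of reproducible signals.
#' @param r0 Minimum correlation at the low end of the reproducible
#'   range, in (0, 1] (e.g. 0.4, 0.6, 0.99).
#' @param mu_ir,sigma_ir Irreproducible-component parameters.
#' @param seed Optional integer seed.
#' @return Same structure as [simulate_bivariate_normal()].
#' @export
simulate_rank_correlated <- function(m = 2860L, pi1, r0, mu_ir = 3.2,
                                     sigma_ir = 0.05, seed = NULL) {
  stopifnot(pi1 > 0, pi1 < 1, r0 > 0, r0 <= 1, sigma_ir > 0)
  n1 <- round(pi1 * m)
  n0 <- m - n1
  with_seed(seed, {
    t1r <- stats::runif(n1, 4, 5)
    r <- (1 - r0) * (t1r - 4) + r0
    t2r <- stats::rnorm(n1, mean = t1r, sd = sqrt(1 - r^2))
    t1 <- c(t1r, stats::rnorm(n0, mu_ir, sigma_ir))
    t2 <- c(t2r, stats::rnorm(n0, mu_ir, sigma_ir))
    list(t1 = t1, t2 = t2,
         reproducible = c(rep(TRUE, n1), rep(FALSE, n0)),
         pi1 = pi1, m = m)
  })
}

#' Bivariate-normal reproducible signals with heavy-tailed noise
#'
#' Identical to [simulate_bivariate_normal()] except that each
#' irreproducible coordinate is an independent Student-t draw with 3
#' degrees of freedom, located at `mu_ir` and scaled by `sigma_ir`, so
#' only the tail weight of the irreproducible component differs from
#' the constant-correlation design.
#'
#' @inheritParams simulate_bivariate_normal
#' @return Same structure as [simulate_bivariate_normal()].
#' @export
simulate_heavy_tailed <- function(m = 2860L, pi1, mu_r, rho_r,
                                  mu_ir = 3.2, sigma_r = 0.17,
                                  sigma_ir = 0.05, seed = NULL) {
  stopifnot(pi1 > 0, pi1 < 1, sigma_r > 0, sigma_ir > 0, abs(rho_r) <= 1)
  n1 <- round(pi1 * m)
  n0 <- m - n1
  with_seed(seed, {
    sigma <- sigma_r^2 * matrix(c(1, rho_r, rho_r, 1), 2L)
    rep_pairs <- MASS::mvrnorm(n1, mu = c(mu_r, mu_r), Sigma = sigma)
    t1 <- c(rep_pairs[, 1L], mu_ir + sigma_ir * stats::rt(n0, df = 3))
    t2 <- c(rep_pairs[, 2L], mu_ir + sigma_ir * stats::rt(n0, df = 3))
    list(t1 = t1, t2 = t2,
         reproducible = c(rep(TRUE, n1), rep(FALSE, n0)),
         pi1 = pi1, m = m)
  })
}

#' Score reproducibility calls against known truth
#'
#' Confusion counts treat "declared reproducible" as a rejection of the
#' irreproducibility null: `fp` counts truly irreproducible metabolites
#' declared reproducible, `fn` truly reproducible metabolites missed.
#' The empirical FDR is `fp / q` with `q = fp + tp` total rejections
#' (0 when nothing is rejected); the non-discovery rate NDR is
#' `fn / (tp + fn)`, and discriminative power is `1 - NDR`.
#'
#' @param calls Integer/logical 0/1 vector of MaRR calls.
#' @param truth Logical (or 0/1) vector of true reproducibility labels.
#' @param pi1_hat,pi1_true Optional estimated and true reproducible
#'   proportions; when given, `bias = pi1_hat - pi1_true` is included.
#' @return An object of class `"marr_score"`: list with counts `tn`,
#'   `fp`, `fn`, `tp`, `q` and metrics `fdr`, `ndr`, `power`, `bias`.
#' @export
score_calls <- function(calls, truth, pi1_hat = NA_real_,
                        pi1_true = NA_real_) {
  if (length(calls) != length(truth)) {
    stop_("'calls' and 'truth' differ in length")
  }
  calls <- as.logical(calls)
  truth <- as.logical(truth)
  tp <- sum(calls & truth)
  fp <- sum(calls & !truth)
  fn <- sum(!calls & truth)
  tn <- sum(!calls & !truth)
  q <- tp + fp
  fdr <- if (q == 0) 0 else fp / q
  ndr <- if (tp + fn == 0) 0 else fn / (tp + fn)
  structure(
    list(tn = tn, fp = fp, fn = fn, tp = tp, q = q,
         fdr = fdr, ndr = ndr, power = 1 - ndr,
         bias = pi1_hat - pi1_true),
    class = "marr_score"
  )
}

#' @export
print.marr_score <- function(x, ...) {
  cat(sprintf("calls: tp %d fp %d fn %d tn %d | FDR %.4f power %.4f",
              x$tp, x$fp, x$fn, x$tn, x$fdr, x$power))
  if (!is.na(x$bias)) cat(sprintf(" bias %+.4f", x$bias))
  cat("\n")
  invisible(x)
}

#' Default simulation setting grids
#'
#' The full factorial parameter grids of the three simulation designs:
#' the constant-correlation bivariate-normal design crosses
#' `mu_r` in \{3.89, 4.01, 4.13\}, `rho_r` in \{0.45, 0.99\} and `pi1`
#' in \{0.2, 0.4, 0.75, 0.9\} (24 settings); the rank-dependent
#' correlation design crosses `pi1` with `r0` in \{0.4, 0.6, 0.99\}
#' (12 settings); the heavy-tailed design reuses the
#' constant-correlation grid.
#'
#' @param design One or more of `"bvnormal"`, `"rankcor"`,
#'   `"heavytail"`.
#' @return Data frame with columns `sim`, `mu_r`, `rho_r`, `r0`, `pi1`
#'   (unused parameters are `NA`).
#' @export
default_sim_grid <- function(design = c("bvnormal", "rankcor",
                                        "heavytail")) {
  design <- match.arg(design, several.ok = TRUE)
  grids <- list()
  pi1 <- c(0.2, 0.4, 0.75, 0.9)
  if ("bvnormal" %in% design) {
    g <- expand.grid(mu_r = c(3.89, 4.01, 4.13), rho_r = c(0.45, 0.99),
                     pi1 = pi1, KEEP.OUT.ATTRS = FALSE)
    grids$bvnormal <- data.frame(sim = "bvnormal", mu_r = g$mu_r,
                                 rho_r = g$rho_r, r0 = NA_real_,
                                 pi1 = g$pi1)
  }
  if ("rankcor" %in% design) {
    g <- expand.grid(r0 = c(0.4, 0.6, 0.99), pi1 = pi1,
                     KEEP.OUT.ATTRS = FALSE)
    grids$rankcor <- data.frame(sim = "rankcor", mu_r = NA_real_,
                                rho_r = NA_real_, r0 = g$r0, pi1 = g$pi1)
  }
  if ("heavytail" %in% design) {
    g <- expand.grid(mu_r = c(3.89, 4.01, 4.13), rho_r = c(0.45, 0.99),
                     pi1 = pi1, KEEP.OUT.ATTRS = FALSE)
    grids$heavytail <- data.frame(sim = "heavytail", mu_r = g$mu_r,
                                  rho_r = g$rho_r, r0 = NA_real_,
                                  pi1 = g$pi1)
  }
  out <- do.call(rbind, grids)
  rownames(out) <- NULL
  out
}

simulate_setting <- function(row, m, seed) {
  switch(as.character(row$sim),
    bvnormal = simulate_bivariate_normal(
      m = m, pi1 = row$pi1, mu_r = row$mu_r, rho_r = row$rho_r,
      seed = seed),
    rankcor = simulate_rank_correlated(
      m = m, pi1 = row$pi1, r0 = row$r0, seed = seed),
    heavytail = simulate_heavy_tailed(
      m = m, pi1 = row$pi1, mu_r = row$mu_r, rho_r = row$rho_r,
      seed = seed),
    stop_("unknown simulation design: ", row$sim)
  )
}

#' Run a simulation study of MaRR operating characteristics
#'
#' For every setting of the grid, generates `n_datasets` simulated
#' replicate pairs, runs [marr_pair()] on each (statistics feed MaRR
#' directly as ranking values, largest = rank 1), scores the calls
#' against the known truth, and aggregates the empirical FDR,
#' discriminative power and bias of the reproducible-proportion
#' estimate. Every dataset and tie-break receives a seed derived from
#' `master_seed`, the setting index and the dataset index, so the whole
#' study is reproducible bit for bit.
#'
#' @param grid Setting grid as from [default_sim_grid()] (columns `sim`,
#'   `mu_r`, `rho_r`, `r0`, `pi1`).
#' @param n_datasets Simulated datasets per setting; 1000 matches the
#'   full study, 100 is a practical scaled-down profile.
#' @param m Metabolites per dataset, default 2860.
#' @param alpha Nominal marginal FDR level, default 0.05.
#' @param lambda Candidate-region bound for [estimate_pi1()].
#' @param master_seed Integer master seed.
#' @return Data frame: the grid columns plus `mean_fdr`, `se_fdr`,
#'   `mean_power`, `mean_ndr`, `mean_bias`, `se_bias`, `n_datasets`.
#' @export
run_study <- function(grid, n_datasets = 100L, m = 2860L, alpha = 0.05,
                      lambda = 0.9, master_seed = 1L) {
  stopifnot(n_datasets >= 1L)
  res <- lapply(seq_len(nrow(grid)), function(j) {
    row <- grid[j, , drop = FALSE]
    fdr <- power <- bias <- numeric(n_datasets)
    for (i in seq_len(n_datasets)) {
      sim <- simulate_setting(row, m = m,
                              seed = derive_seed(master_seed, j, i, 1L))
      fit <- marr_pair(sim$t1, sim$t2, alpha = alpha, lambda = lambda,
                       tie_seed = derive_seed(master_seed, j, i, 2L))
      sc <- score_calls(fit$calls, sim$reproducible,
                        pi1_hat = fit$pi1_hat, pi1_true = sim$pi1)
      fdr[i] <- sc$fdr
      power[i] <- sc$power
      bias[i] <- sc$bias
    }
    cbind(row,
          data.frame(mean_fdr = mean(fdr),
                     se_fdr = stats::sd(fdr) / sqrt(n_datasets),
                     mean_power = mean(power),
                     mean_ndr = 1 - mean(power),
                     mean_bias = mean(bias),
                     se_bias = stats::sd(bias) / sqrt(n_datasets),
                     n_datasets = n_datasets))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Relative standard deviation of replicate measurements
#'
#' `RSD = 100 * sd / |mean|`, the conventional QC filter statistic;
#' `sd` is the sample (n-1) standard deviation.
#'
#' @param values Numeric vector of at least 2 replicate measurements
#'   with nonzero mean.
#' @return RSD in percent.
#' @export
#' @examples
#' rsd(c(8, 10, 12))
rsd <- function(values) {
  if (length(values) < 2L) stop_("RSD needs at least 2 values")
  mu <- mean(values)
  if (mu == 0) stop_("RSD is undefined for a zero mean")
  100 * stats::sd(values) / abs(mu)
}

#' Compare MaRR reproducibility calls with the RSD filter
#'
#' Joins each metabolite's RSD across samples with its MaRR
#' reproducibility flag and tabulates how the conventional RSD cutoff
#' treats the metabolites MaRR labels irreproducible: an irreproducible
#' metabolite with RSD at or below the cutoff survives RSD filtering
#' (is "retained"), one above the cutoff is removed.
#'
#' @param x Abundance table or matrix (features x samples).
#' @param repro_flags Binary vector of MaRR reproducibility flags, one
#'   per feature (e.g. from [metabolite_reproducibility()]).
#' @param rsd_cutoff RSD filtering cutoff in percent, default 25.
#' @return List with `table` (per-metabolite data frame: `feature_id`,
#'   `rsd`, `marr_reproducible`, `rsd_pass`) and the four cross counts
#'   `removed_irreproducible`, `retained_irreproducible`,
#'   `removed_reproducible`, `retained_reproducible`.
#' @export
rsd_comparison <- function(x, repro_flags, rsd_cutoff = 25) {
  v <- pp_values(x)
  if (length(repro_flags) != nrow(v)) {
    stop_("'repro_flags' must have one entry per feature")
  }
  flags <- as.integer(as.logical(repro_flags))
  rsd_vals <- apply(v, 1L, rsd)
  pass <- rsd_vals <= rsd_cutoff
  tab <- data.frame(feature_id = rownames(v) %||%
                      paste0("feature", seq_len(nrow(v))),
                    rsd = rsd_vals, marr_reproducible = flags,
                    rsd_pass = pass, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       removed_irreproducible = sum(!pass & flags == 0L),
       retained_irreproducible = sum(pass & flags == 0L),
       removed_reproducible = sum(!pass & flags == 1L),
       retained_reproducible = sum(pass & flags == 1L))
}
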