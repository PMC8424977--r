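# Preprocessing for MS-metabolomics abundance tables: missing-value
# filtering, kNN imputation, normalization, outlier-sample removal and
# log transformation. All steps accept either a "marr_abundance" table
# or a bare features x samples matrix and return the same kind.

pp_values <- function(x) {
  if (inherits(x, "marr_abundance")) x$values else as.matrix(x)
}

pp_rebuild <- function(x, values, keep_samples = NULL) {
  if (!inherits(x, "marr_abundance")) return(values)
  coords <- x$coordinates
  if (!is.null(keep_samples)) {
    coords <- coords[coords$sample_id %in% keep_samples, , drop = FALSE]
  }
  abundance_table(values, coords, layers = x$layers)
}

#' Remove features with too many missing values
#'
#' Drops every feature whose fraction of missing samples is strictly
#' greater than `max_missing_fraction`; a feature missing in exactly
#' that fraction of samples is retained. The removed feature ids are
#' attached as attribute `"removed_features"`.
#'
#' @param x Abundance table or matrix (features x samples).
#' @param max_missing_fraction Maximum tolerated missing fraction,
#'   default 0.2 (the conventional 20 percent rule).
#' @return Filtered table of the same kind as `x`.
#' @export
filter_missing <- function(x, max_missing_fraction = 0.2) {
  v <- pp_values(x)
  frac <- rowMeans(is.na(v))
  keep <- frac <= max_missing_fraction
  if (!any(keep)) stop_("all features exceed the missing-value threshold")
  removed <- rownames(v)[!keep]
  message(length(removed), " of ", nrow(v),
          " features removed (> ", 100 * max_missing_fraction,
          "% missing)")
  out <- pp_rebuild(x, v[keep, , drop = FALSE])
  attr(out, "removed_features") <- removed
  out
}

#' Impute missing abundances by k nearest neighbour features
#'
#' For each feature with missing cells, the `k` nearest features are
#' found by Euclidean distance between feature profiles, computed over
#' pairwise-complete samples and rescaled to the full profile length so
#' that distances with different overlap are comparable. Each missing
#' cell is replaced by the mean of the neighbours' observed values in
#' that sample. Degenerate cases -- no candidate shares at least two
#' observed samples, or no neighbour is observed in the target sample --
#' fall back to the feature's own observed mean.
#'
#' @param x Abundance table or matrix; every feature must have at least
#'   one observed value (filter first, see [filter_missing()]).
#' @param k Number of neighbours, default 5.
#' @return Fully observed table of the same kind as `x`.
#' @export
impute_knn <- function(x, k = 5L) {
  v <- pp_values(x)
  if (k < 1L) stop_("'k' must be at least 1")
  all_missing <- rowSums(!is.na(v)) == 0L
  if (any(all_missing)) {
    stop_("feature(s) with no observed values: ",
          paste(utils::head(rownames(v)[all_missing], 5L), collapse = ", "),
          "; remove them with filter_missing() first")
  }
  obs <- !is.na(v)
  targets <- which(rowSums(obs) < ncol(v))
  for (f in targets) {
    diff2 <- sweep(v, 2L, v[f, ])^2              # NA where either missing
    joint <- obs & matrix(obs[f, ], nrow(v), ncol(v), byrow = TRUE)
    n_joint <- rowSums(joint)
    d2 <- rowMeans(diff2, na.rm = TRUE) * ncol(v)
    d2[f] <- Inf
    d2[n_joint < 2L] <- Inf
    if (all(is.infinite(d2))) {
      v[f, !obs[f, ]] <- mean(v[f, obs[f, ]])
      next
    }
    nb <- order(d2)[seq_len(min(k, sum(is.finite(d2))))]
    for (s in which(!obs[f, ])) {
      vals <- v[nb, s]
      vals <- vals[!is.na(vals)]
      v[f, s] <- if (length(vals)) mean(vals) else mean(v[f, obs[f, ]])
    }
  }
  pp_rebuild(x, v)
}

#' Quantile normalization across samples
#'
#' Forces every sample to share the same distribution of values: the
#' i-th smallest value in each sample is replaced by the mean of the
#' i-th smallest values over all samples (tied within-sample values
#' receive the mean of the reference values at the tied positions).
#' Delegates to [limma::normalizeQuantiles()]. Within-sample ranks are
#' preserved, so downstream MaRR calls on a replicate pair are
#' unaffected by this step.
#'
#' @param x Fully observed abundance table or matrix.
#' @return Normalized table of the same kind as `x`.
#' @export
normalize_quantile <- function(x) {
  v <- pp_values(x)
  if (anyNA(v)) stop_("missing values present; impute before normalizing")
  out <- limma::normalizeQuantiles(v, ties = TRUE)
  dimnames(out) <- dimnames(v)
  pp_rebuild(x, out)
}

#' Median normalization across samples
#'
#' Divides each sample by its own median and multiplies by the grand
#' median of all values, so every sample ends with the same median.
#'
#' @param x Fully observed abundance table or matrix with positive
#'   values.
#' @return Normalized table of the same kind as `x`.
#' @export
normalize_median <- function(x) {
  v <- pp_values(x)
  if (anyNA(v)) stop_("missing values present; impute before normalizing")
  med <- apply(v, 2L, stats::median)
  if (any(med == 0)) {
    stop_("sample(s) with zero median: ",
          paste(colnames(v)[med == 0], collapse = ", "))
  }
  grand <- stats::median(v)
  pp_rebuild(x, sweep(v, 2L, med, "/") * grand)
}

#' Run-day normalization per metabolite
#'
#' Corrects inter-day instrument drift: each metabolite's value is
#' divided by that metabolite's median within its run day and multiplied
#' by the metabolite's overall median.
#'
#' @param x Fully observed abundance table or matrix.
#' @param runday Character or factor vector assigning each sample
#'   (column) to a run day.
#' @return Normalized table of the same kind as `x`.
#' @export
normalize_runday <- function(x, runday) {
  v <- pp_values(x)
  if (anyNA(v)) stop_("missing values present; impute before normalizing")
  if (length(runday) != ncol(v)) {
    stop_("'runday' must have one entry per sample")
  }
  runday <- as.character(runday)
  out <- v
  overall <- apply(v, 1L, stats::median)
  for (day in unique(runday)) {
    idx <- runday == day
    day_med <- apply(v[, idx, drop = FALSE], 1L, stats::median)
    if (any(day_med == 0)) {
      stop_("zero run-day median for feature(s) on day ", day)
    }
    out[, idx] <- v[, idx, drop = FALSE] / day_med * overall
  }
  pp_rebuild(x, out)
}

#' Remove outlying samples by aggregate median z-score
#'
#' Computes each sample's median abundance across metabolites, z-scores
#' these medians over samples, and drops samples whose absolute z-score
#' exceeds the threshold. Dropped sample ids are attached as attribute
#' `"removed_samples"`.
#'
#' @param x Abundance table or matrix with at least 3 samples.
#' @param z_threshold Absolute z-score cutoff, default 3.5.
#' @return Table of the same kind as `x` without the outlying samples.
#' @export
remove_outlier_samples <- function(x, z_threshold = 3.5) {
  v <- pp_values(x)
  if (ncol(v) < 3L) stop_("outlier screening needs at least 3 samples")
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  s <- stats::sd(med)
  z <- if (is.na(s) || s == 0) rep(0, length(med)) else (med - mean(med)) / s
  drop <- abs(z) > z_threshold
  if (any(drop)) {
    message(sum(drop), " outlier sample(s) removed: ",
            paste(colnames(v)[drop], collapse = ", "))
  }
  out <- pp_rebuild(x, v[, !drop, drop = FALSE],
                    keep_samples = colnames(v)[!drop])
  attr(out, "removed_samples") <- colnames(v)[drop]
  out
}

#' Log-transform abundances
#'
#' Elementwise logarithm, default base 2. The choice of base is
#' irrelevant for the rank-based MaRR steps downstream; it only affects
#' the scale of exported matrices.
#'
#' @param x Abundance table or matrix of strictly positive values
#'   (missing values pass through).
#' @param base Logarithm base, default 2.
#' @return Transformed table of the same kind as `x`.
#' @export
log_transform <- function(x, base = 2) {
  v <- pp_values(x)
  bad <- which(!is.na(v) & v <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_("nonpositive abundance for feature '", rownames(v)[bad[1L, 1L]],
          "', sample '", colnames(v)[bad[1L, 2L]],
          "': cannot log-transform")
  }
  pp_rebuild(x, log(v, base = base))
}
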