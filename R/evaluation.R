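# Assembling per-pair MaRR calls into the metabolite x pair
# reproducibility matrix and the data-driven filtering summaries.

#' Construct a reproducibility call matrix
#'
#' Wraps an M x J binary matrix of per-pair MaRR calls (rows =
#' metabolites, columns = replicate sample pairs at one design layer).
#'
#' @param calls Binary (0/1) matrix, or a list of `"marr_pair"` results
#'   with equal `m_total` whose call vectors become the columns.
#' @param feature_ids,pair_ids Optional dimension ids; taken from
#'   dimnames or the pair results when available.
#' @param layer Optional label of the design layer the pairs belong to.
#' @return An object of class `"marr_calls"`: list with `calls`,
#'   `feature_ids`, `pair_ids`, `layer`.
#' @export
repro_matrix <- function(calls, feature_ids = NULL, pair_ids = NULL,
                         layer = NULL) {
  if (is.list(calls) && !is.matrix(calls)) {
    stopifnot(all(vapply(calls, inherits, logical(1), "marr_pair")))
    pair_ids <- pair_ids %||%
      vapply(calls, function(p) paste(p$pair_id %||% "?", collapse = "|"),
             character(1))
    calls <- vapply(calls, `[[`, integer(calls[[1L]]$m_total), "calls")
  }
  calls <- as.matrix(calls)
  if (!all(calls %in% c(0L, 1L))) stop_("calls must be binary 0/1")
  storage.mode(calls) <- "integer"
  feature_ids <- feature_ids %||% rownames(calls) %||%
    paste0("feature", seq_len(nrow(calls)))
  pair_ids <- pair_ids %||% colnames(calls) %||%
    paste0("pair", seq_len(ncol(calls)))
  dimnames(calls) <- list(feature_ids, pair_ids)
  structure(
    list(calls = calls, feature_ids = feature_ids, pair_ids = pair_ids,
         layer = layer),
    class = "marr_calls"
  )
}

#' @export
print.marr_calls <- function(x, ...) {
  cat("Reproducibility calls:", nrow(x$calls), "metabolites x",
      ncol(x$calls), "sample pairs",
      if (!is.null(x$layer)) paste0("(layer ", x$layer, ")") else "", "\n")
  cat(sprintf("  overall reproducible fraction: %.3f\n", mean(x$calls)))
  invisible(x)
}

#' Flag reproducible metabolites across sample pairs
#'
#' A metabolite is reproducible when the fraction of sample pairs in
#' which it was called reproducible is *strictly* greater than `c_s`.
#'
#' @param x A `"marr_calls"` object (or binary matrix).
#' @param c_s Fraction threshold in (0, 1).
#' @return Named integer 0/1 vector over metabolites.
#' @export
metabolite_reproducibility <- function(x, c_s) {
  calls <- if (inherits(x, "marr_calls")) x$calls else as.matrix(x)
  check_fraction(c_s, "c_s")
  out <- as.integer(rowMeans(calls) > c_s)
  names(out) <- rownames(calls)
  out
}

#' Flag reproducible sample pairs across metabolites
#'
#' A sample pair is reproducible when the fraction of metabolites called
#' reproducible in that pair is *strictly* greater than `c_m`.
#'
#' @param x A `"marr_calls"` object (or binary matrix).
#' @param c_m Fraction threshold in (0, 1).
#' @return Named integer 0/1 vector over pairs.
#' @export
pair_reproducibility <- function(x, c_m) {
  calls <- if (inherits(x, "marr_calls")) x$calls else as.matrix(x)
  check_fraction(c_m, "c_m")
  out <- as.integer(colMeans(calls) > c_m)
  names(out) <- colnames(calls)
  out
}

check_fraction <- function(v, label) {
  if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
    stop_("'", label, "' must be a single fraction strictly in (0, 1)")
  }
  invisible(TRUE)
}

#' Summary of reproducibility at standard thresholds
#'
#' For each threshold `t`, reports the percentage of sample pairs whose
#' reproducible-metabolite fraction exceeds `t` and the percentage of
#' metabolites whose reproducible-pair fraction exceeds `t`
#' (strict inequalities), rounded to two decimals.
#'
#' @param x A `"marr_calls"` object (or binary matrix).
#' @param thresholds Numeric vector of fractions, default
#'   `c(0.7, 0.8, 0.9)`.
#' @return Data frame with columns `threshold`,
#'   `pct_reproducible_pairs` and `pct_reproducible_metabolites`.
#' @export
summary_table <- function(x, thresholds = c(0.7, 0.8, 0.9)) {
  calls <- if (inherits(x, "marr_calls")) x$calls else as.matrix(x)
  col_frac <- colMeans(calls)
  row_frac <- rowMeans(calls)
  data.frame(
    threshold = thresholds,
    pct_reproducible_pairs =
      round(100 * vapply(thresholds, function(t) mean(col_frac > t),
                         numeric(1)), 2L),
    pct_reproducible_metabolites =
      round(100 * vapply(thresholds, function(t) mean(row_frac > t),
                         numeric(1)), 2L)
  )
}

#' Percent-scale histogram data for reproducibility margins
#'
#' Per-unit reproducible percentages (per metabolite across pairs, or
#' per pair across metabolites) together with fixed-width bin counts for
#' plotting or export.
#'
#' @param x A `"marr_calls"` object (or binary matrix).
#' @param margin `"metabolites"` (rows) or `"pairs"` (columns).
#' @param binwidth Bin width in percent, default 10.
#' @return List with `percent` (per-unit values), `breaks`, `counts`
#'   and `mids`; the counts sum to the number of units.
#' @export
histogram_data <- function(x, margin = c("metabolites", "pairs"),
                           binwidth = 10) {
  calls <- if (inherits(x, "marr_calls")) x$calls else as.matrix(x)
  margin <- match.arg(margin)
  pct <- 100 * if (margin == "metabolites") rowMeans(calls) else
    colMeans(calls)
  breaks <- seq(0, 100, by = binwidth)
  h <- graphics::hist(pct, breaks = breaks, include.lowest = TRUE,
                      right = TRUE, plot = FALSE)
  list(percent = pct, breaks = h$breaks, counts = h$counts, mids = h$mids)
}

#' Run MaRR over every replicate pair of a layer
#'
#' Enumerates the replicate pairs of the table's bottom layer, runs
#' [marr_pair()] on each, and assembles the calls into a reproducibility
#' matrix. Tie-breaking seeds are derived from `master_seed` and the
#' pair index, so a full run is reproducible bit for bit.
#'
#' @param table A fully observed `"marr_abundance"` object.
#' @param layer Layer to pair at; defaults to the bottom layer.
#' @param alpha Nominal marginal FDR level (0.01 is the conservative
#'   real-data default, 0.05 the usual simulation level).
#' @param lambda Candidate-region bound for [estimate_pi1()].
#' @param master_seed Integer master seed for tie-breaking.
#' @return List with `matrix` (a `"marr_calls"` object) and `pairs`
#'   (data frame of per-pair estimates: `pair_id`, `group`, `k_hat`,
#'   `pi1_hat`, `n_hat`, `n_reproducible`).
#' @export
marr_layer <- function(table, layer = NULL, alpha = 0.01, lambda = 0.9,
                       master_seed = 1L) {
  stopifnot(inherits(table, "marr_abundance"))
  if (anyNA(table$values)) stop_("missing values present; impute first")
  pairs <- enumerate_pairs(table, layer)
  m <- nrow(table$values)
  calls <- matrix(0L, m, nrow(pairs),
                  dimnames = list(rownames(table$values), pairs$pair_id))
  stats <- vector("list", nrow(pairs))
  for (j in seq_len(nrow(pairs))) {
    res <- marr_pair(table$values[, pairs$sample_a[j]],
                     table$values[, pairs$sample_b[j]],
                     alpha = alpha, lambda = lambda,
                     tie_seed = derive_seed(master_seed, j),
                     pair_id = c(pairs$sample_a[j], pairs$sample_b[j]))
    calls[, j] <- res$calls
    stats[[j]] <- data.frame(pair_id = pairs$pair_id[j],
                             group = pairs$group[j],
                             k_hat = res$k_hat, pi1_hat = res$pi1_hat,
                             n_hat = res$n_hat,
                             n_reproducible = sum(res$calls),
                             stringsAsFactors = FALSE)
  }
  list(matrix = repro_matrix(calls,
                             layer = layer %||%
                               table$layers[length(table$layers)]),
       pairs = do.call(rbind, stats))
}
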