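# File I/O: delimited abundance matrices with sample metadata, synthetic
# fixture generation, and the end-to-end reproducibility pipeline.

read_delim_auto <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    na.strings = c("NA", ""), check.names = FALSE,
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Read an abundance matrix with sample metadata
#'
#' The abundance file is delimited text (comma for `.csv`, tab for
#' `.tsv`/`.txt`) with a feature-id first column and one column per
#' sample; missing cells are empty or `NA`. The metadata file has a
#' `sample_id` column plus one column per design layer, top layer
#' first. Lines starting with `#` are treated as comments.
#'
#' @param path Path to the abundance matrix.
#' @param metadata_path Optional path to the sample metadata; when
#'   omitted a single-layer design is assumed.
#' @return A `"marr_abundance"` object.
#' @export
read_abundance <- function(path, metadata_path = NULL) {
  df <- read_delim_auto(path)
  if (ncol(df) < 2L) stop_("abundance file needs a feature column and samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_("duplicate feature ids in ", path, ": ",
          paste(utils::head(unique(ids[duplicated(ids)]), 5L),
                collapse = ", "))
  }
  vals <- df[, -1L, drop = FALSE]
  # a column that is entirely missing is read as logical NA
  all_na <- vapply(vals, function(col) is.logical(col) && all(is.na(col)),
                   logical(1))
  vals[all_na] <- lapply(vals[all_na], as.numeric)
  non_num <- !vapply(vals, is.numeric, logical(1))
  if (any(non_num)) {
    stop_("non-numeric abundance column(s): ",
          paste(names(vals)[non_num], collapse = ", "))
  }
  mat <- as.matrix(vals)
  rownames(mat) <- ids
  coords <- if (!is.null(metadata_path)) read_delim_auto(metadata_path)
  abundance_table(mat, coords)
}

#' Write an abundance table to delimited text
#'
#' @param table A `"marr_abundance"` object or matrix.
#' @param path Output path (`.csv` or `.tsv`).
#' @param provenance Optional character vector written as leading `#`
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(table, path, provenance = NULL) {
  v <- pp_values(table)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_table_prov(df, path, provenance)
}

write_table_prov <- function(df, path, provenance = NULL) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(df, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic nested-design fixture on disk
#'
#' Writes an abundance matrix, sample metadata and a truth file
#' emulating a hierarchical replicate design with planted reproducible
#' and irreproducible features. On the log scale, each reproducible
#' feature has a latent level shared by every sample
#' (`N(mu_r, rho_r * sigma_r^2)`) plus independent per-sample noise, so
#' that any two samples have correlation `rho_r` for that feature;
#' irreproducible features are independent `N(mu_ir, sigma_ir^2)` draws
#' per sample. Values are exported as raw abundances (`2^stat`) and a
#' fraction of cells is set missing completely at random so the
#' filtering and imputation steps are exercised.
#'
#' @param dir Output directory (created if needed).
#' @param layers Named integer vector of level counts, top layer first,
#'   e.g. `c(operator = 3, spikein = 3, replicate = 3)`.
#' @param n_features Number of features, default 200.
#' @param pi1 Planted proportion of reproducible features.
#' @param mu_r,rho_r,sigma_r,mu_ir,sigma_ir Generator parameters on the
#'   log2 scale (see [simulate_bivariate_normal()] for their meaning).
#' @param missing_rate Fraction of cells set missing, default 0.05.
#' @param seed Integer seed.
#' @return Invisibly, a list with paths `abundance`, `metadata`,
#'   `truth`.
#' @export
generate_fixture <- function(dir, layers = c(operator = 3L, spikein = 3L,
                                             replicate = 3L),
                             n_features = 200L, pi1 = 0.75, mu_r = 4.01,
                             rho_r = 0.99, sigma_r = 0.17, mu_ir = 3.2,
                             sigma_ir = 0.05, missing_rate = 0.05,
                             seed = 1L) {
  stopifnot(length(layers) >= 1L, all(layers >= 1L), !is.null(names(layers)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coords <- expand.grid(lapply(rev(layers), function(n) {
    sprintf("%d", seq_len(n))
  }), KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  coords <- coords[, rev(seq_along(layers)), drop = FALSE]
  names(coords) <- names(layers)
  for (nm in names(layers)) coords[[nm]] <- paste0(nm, coords[[nm]])
  sample_id <- apply(coords, 1L, paste, collapse = "_")
  n_samples <- length(sample_id)
  n1 <- round(pi1 * n_features)
  n0 <- n_features - n1
  with_seed(seed, {
    latent <- stats::rnorm(n1, mu_r, sqrt(rho_r) * sigma_r)
    noise <- matrix(stats::rnorm(n1 * n_samples, 0,
                                 sqrt(1 - rho_r) * sigma_r),
                    n1, n_samples)
    repro <- latent + noise
    irrep <- matrix(stats::rnorm(n0 * n_samples, mu_ir, sigma_ir),
                    n0, n_samples)
    stat <- rbind(repro, irrep)
    raw <- 2^stat
    if (missing_rate > 0) {
      holes <- stats::runif(length(raw)) < missing_rate
      raw[holes] <- NA_real_
    }
    rownames(raw) <- sprintf("met%04d", seq_len(n_features))
    colnames(raw) <- sample_id
    meta <- cbind(data.frame(sample_id = sample_id,
                             stringsAsFactors = FALSE), coords)
    truth <- data.frame(feature_id = rownames(raw),
                        reproducible = rep(c(1L, 0L), c(n1, n0)))
    paths <- list(abundance = file.path(dir, "abundance.csv"),
                  metadata = file.path(dir, "metadata.csv"),
                  truth = file.path(dir, "truth.csv"))
    write_abundance(raw, paths$abundance)
    write_table_prov(meta, paths$metadata)
    write_table_prov(truth, paths$truth)
    invisible(paths)
  })
}

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pkg_version <- function() {
  as.character(utils::packageVersion("marrqc"))
}

#' Run the data-driven reproducibility pipeline
#'
#' End-to-end workflow: read the abundance matrix and design metadata,
#' filter features by missingness, impute by kNN (unless the matrix is
#' already complete or `preimputed = TRUE`), normalize, then for every
#' design layer from the bottom upwards pool the layers beneath it,
#' log-transform, run MaRR over all replicate pairs of the layer, and
#' write the reproducibility matrix, margin flags, summary table and
#' histogram data. Finally the features flagged reproducible at the
#' bottom layer (fraction of pairs > `c_s`) are subset into an
#' analysis-ready matrix. Every output carries a provenance header with
#' the package version, configuration hash and master seed.
#'
#' @param abundance Path to the abundance matrix, or a
#'   `"marr_abundance"` object.
#' @param metadata Path to the sample metadata (ignored when
#'   `abundance` is already a table).
#' @param out_dir Output directory.
#' @param alpha Marginal FDR level; the conservative 0.01 default suits
#'   real data.
#' @param lambda Candidate-region bound for [estimate_pi1()].
#' @param c_s Fraction threshold flagging a metabolite reproducible
#'   across pairs (strict).
#' @param c_m Fraction threshold flagging a sample pair reproducible
#'   across metabolites (strict).
#' @param normalization One of `"quantile"`, `"median"`, `"runday"`,
#'   `"none"`.
#' @param runday Run-day labels per sample (required for
#'   `normalization = "runday"`).
#' @param max_missing Missing-fraction filter threshold.
#' @param knn_k Neighbours for imputation.
#' @param log_base Base of the log transform applied before MaRR.
#' @param outlier_z Optional absolute z-score for dropping outlier
#'   samples before anything else (`NULL` disables the step).
#' @param preimputed Set `TRUE` when the matrix was imputed externally
#'   (e.g. BPCA or random-forest imputation); filtering and kNN are
#'   then skipped.
#' @param seed Master seed for tie-breaking.
#' @return Invisibly, a list with the processed table, per-layer
#'   results (`marr_layer()` output plus flags and summaries) and the
#'   paths written.
#' @export
run_pipeline <- function(abundance, metadata = NULL, out_dir,
                         alpha = 0.01, lambda = 0.9, c_s = 0.7,
                         c_m = 0.7,
                         normalization = c("quantile", "median",
                                           "runday", "none"),
                         runday = NULL, max_missing = 0.2, knn_k = 5L,
                         log_base = 2, outlier_z = NULL,
                         preimputed = FALSE, seed = 1L) {
  normalization <- match.arg(normalization)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(alpha = alpha, lambda = lambda, c_s = c_s, c_m = c_m,
                 normalization = normalization, max_missing = max_missing,
                 knn_k = knn_k, log_base = log_base,
                 outlier_z = outlier_z, preimputed = preimputed,
                 seed = seed)
  prov <- sprintf("marrqc %s | config %s | seed %d", pkg_version(),
                  config_hash(config), as.integer(seed))
  log_lines <- c(prov, paste0("config: ", jsonlite::toJSON(config,
                                                           auto_unbox = TRUE,
                                                           null = "null")))

  tab <- if (inherits(abundance, "marr_abundance")) abundance else
    read_abundance(abundance, metadata)
  log_lines <- c(log_lines, sprintf("input: %d features x %d samples",
                                    nrow(tab$values), ncol(tab$values)))

  if (!is.null(outlier_z)) {
    tab <- remove_outlier_samples(tab, z_threshold = outlier_z)
    log_lines <- c(log_lines, sprintf("outlier screen: %d samples kept",
                                      ncol(tab$values)))
  }
  if (!preimputed) {
    tab <- filter_missing(tab, max_missing_fraction = max_missing)
    log_lines <- c(log_lines, sprintf("filter: %d features kept",
                                      nrow(tab$values)))
    if (anyNA(tab$values)) tab <- impute_knn(tab, k = knn_k)
    log_lines <- c(log_lines, "impute: matrix complete")
  } else if (anyNA(tab$values)) {
    stop_("'preimputed = TRUE' but the matrix still has missing values")
  }
  tab <- switch(normalization,
    quantile = normalize_quantile(tab),
    median = normalize_median(tab),
    runday = {
      if (is.null(runday)) stop_("'runday' labels required")
      normalize_runday(tab, runday)
    },
    none = tab
  )
  log_lines <- c(log_lines, paste0("normalize: ", normalization))

  layers <- tab$layers
  layer_results <- list()
  for (d in rev(seq_along(layers))) {
    layer <- layers[d]
    layer_tab <- if (d == length(layers)) tab else
      pool_lower_layers(tab, layer)
    # skip layers that cannot be paired (single unit per group)
    n_units <- ncol(layer_tab$values)
    if (n_units < 2L) {
      log_lines <- c(log_lines, sprintf(
        "layer %s: %d unit(s), skipped (nothing to pair)", layer, n_units))
      next
    }
    layer_log <- log_transform(layer_tab, base = log_base)
    res <- marr_layer(layer_log, layer = layer, alpha = alpha,
                      lambda = lambda,
                      master_seed = derive_seed(seed, d))
    rm_obj <- res$matrix
    met_flags <- metabolite_reproducibility(rm_obj, c_s)
    pair_flags <- pair_reproducibility(rm_obj, c_m)
    summ <- summary_table(rm_obj)
    hists <- list(metabolites = histogram_data(rm_obj, "metabolites"),
                  pairs = histogram_data(rm_obj, "pairs"))
    pfx <- file.path(out_dir, layer)
    write_table_prov(data.frame(feature_id = rownames(rm_obj$calls),
                                rm_obj$calls, check.names = FALSE),
                     paste0(pfx, "_repro_matrix.csv"), prov)
    write_table_prov(data.frame(feature_id = names(met_flags),
                                reproducible = met_flags),
                     paste0(pfx, "_metabolite_flags.csv"), prov)
    write_table_prov(data.frame(pair_id = names(pair_flags),
                                reproducible = pair_flags),
                     paste0(pfx, "_pair_flags.csv"), prov)
    write_table_prov(summ, paste0(pfx, "_summary.csv"), prov)
    jsonlite::write_json(
      list(provenance = prov, layer = layer, histograms = hists),
      paste0(pfx, "_histograms.json"), auto_unbox = TRUE, digits = NA)
    log_lines <- c(log_lines, sprintf(
      "layer %s: %d pairs, median pi1_hat %.3f, %d/%d metabolites flagged",
      layer, ncol(rm_obj$calls), stats::median(res$pairs$pi1_hat),
      sum(met_flags), length(met_flags)))
    layer_results[[layer]] <- list(result = res, metabolite_flags = met_flags,
                                   pair_flags = pair_flags, summary = summ,
                                   histograms = hists)
  }

  bottom <- layers[length(layers)]
  subset_path <- NULL
  if (bottom %in% names(layer_results)) {
    flags <- layer_results[[bottom]]$metabolite_flags
    keep <- names(flags)[flags == 1L]
    subset_tab <- log_transform(tab, base = log_base)
    subset_path <- file.path(out_dir, "reproducible_subset.csv")
    write_abundance(subset_tab$values[keep, , drop = FALSE], subset_path,
                    provenance = prov)
    log_lines <- c(log_lines, sprintf("subset: %d reproducible features",
                                      length(keep)))
  }
  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(table = tab, layers = layer_results,
                 subset_path = subset_path, out_dir = out_dir,
                 provenance = prov, log = log_lines))
}
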