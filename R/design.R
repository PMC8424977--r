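# Hierarchical (multi-layer) replicate designs: the abundance container,
# replicate-pair enumeration, and pooling of lower layers.

#' Construct an abundance table with layer coordinates
#'
#' The central data container: a features x samples numeric matrix plus
#' a per-sample coordinate table placing each sample in a nested study
#' design. Layers are ordered top to bottom (e.g. operator > spike-in >
#' technical replicate); the bottom layer indexes the replicate
#' experiments that are actually measured.
#'
#' @param values Numeric matrix, features in rows and samples in
#'   columns. Row names are the feature (metabolite) ids, column names
#'   the sample ids; both are required and must be unique. Missing
#'   abundances are `NA`.
#' @param coordinates Optional data frame with a `sample_id` column plus
#'   one column per layer, top layer first. When omitted, a single layer
#'   named `"replicate"` is created with each sample its own replicate.
#' @param layers Optional character vector naming (and ordering) the
#'   layer columns of `coordinates`; defaults to all non-`sample_id`
#'   columns in their given order.
#' @return An object of class `"marr_abundance"`: list with `values`,
#'   `coordinates`, `layers`, `feature_ids`, `sample_ids`.
#' @export
#' @examples
#' x <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("met", 1:4), paste0("s", 1:3)))
#' abundance_table(x)
abundance_table <- function(values, coordinates = NULL, layers = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("abundance values must be numeric")
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_("the abundance matrix needs feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    stop_("duplicate feature ids: ",
          paste(unique(rownames(values)[duplicated(rownames(values))]),
                collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) stop_("duplicate sample ids")
  if (is.null(coordinates)) {
    coordinates <- data.frame(sample_id = colnames(values),
                              replicate = colnames(values),
                              stringsAsFactors = FALSE)
  }
  coordinates <- as.data.frame(coordinates, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(coordinates)) {
    stop_("'coordinates' must contain a sample_id column")
  }
  layers <- layers %||% setdiff(names(coordinates), "sample_id")
  if (length(layers) < 1L) stop_("the design needs at least one layer")
  missing_cols <- setdiff(layers, names(coordinates))
  if (length(missing_cols)) {
    stop_("layer column(s) absent from metadata: ",
          paste(missing_cols, collapse = ", "))
  }
  coordinates <- coordinates[, c("sample_id", layers), drop = FALSE]
  unmatched <- setdiff(colnames(values), coordinates$sample_id)
  if (length(unmatched)) {
    stop_("sample(s) missing from metadata: ",
          paste(unmatched, collapse = ", "))
  }
  coordinates <-
    coordinates[match(colnames(values), coordinates$sample_id), , drop = FALSE]
  rownames(coordinates) <- NULL
  key <- do.call(paste, c(coordinates[layers], sep = "\r"))
  if (anyDuplicated(key)) {
    stop_("layer coordinates are not unique per sample")
  }
  structure(
    list(values = values, coordinates = coordinates, layers = layers,
         feature_ids = rownames(values), sample_ids = colnames(values)),
    class = "marr_abundance"
  )
}

#' @export
print.marr_abundance <- function(x, ...) {
  cat("Abundance table:", nrow(x$values), "features x",
      ncol(x$values), "samples\n")
  cat("  layers (top to bottom):", paste(x$layers, collapse = " > "), "\n")
  n_miss <- sum(is.na(x$values))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", n_miss,
              100 * n_miss / length(x$values)))
  invisible(x)
}

#' Enumerate replicate pairs at a design layer
#'
#' Reproducibility is assessed over all unordered pairs of replicate
#' units at one layer, separately within each combination of the layers
#' above it. The named layer must be the bottom layer of the table, so
#' that each sample is one unit; to compare units of an upper layer,
#' first pool the layers beneath it with [pool_lower_layers()].
#'
#' @param table A `"marr_abundance"` object.
#' @param layer Name of the layer to pair at (the table's bottom layer).
#' @return Data frame with one row per pair: `group` (concatenated
#'   upper-layer coordinates, `""` for the top layer), `sample_a`,
#'   `sample_b`, `pair_id`.
#' @export
enumerate_pairs <- function(table, layer = NULL) {
  stopifnot(inherits(table, "marr_abundance"))
  layer <- layer %||% table$layers[length(table$layers)]
  if (!layer %in% table$layers) stop_("unknown layer: ", layer)
  if (layer != table$layers[length(table$layers)]) {
    stop_("'", layer, "' is not the bottom layer of this table; ",
          "pool the layers beneath it first (see pool_lower_layers)")
  }
  upper <- table$layers[seq_len(match(layer, table$layers) - 1L)]
  coords <- table$coordinates
  group <- if (length(upper)) {
    do.call(paste, c(coords[upper], sep = "."))
  } else {
    rep("", nrow(coords))
  }
  out <- lapply(split(coords$sample_id, group), function(ids) {
    if (length(ids) < 2L) {
      stop_("a group at layer '", layer, "' has a single replicate; ",
            "pairing needs >= 2 units -- pool this layer instead")
    }
    cmb <- utils::combn(sort(ids), 2L)
    data.frame(sample_a = cmb[1L, ], sample_b = cmb[2L, ],
               stringsAsFactors = FALSE)
  })
  grp <- rep(names(out), vapply(out, nrow, integer(1)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- cbind(data.frame(group = grp, stringsAsFactors = FALSE), out)
  out$pair_id <- paste(out$sample_a, out$sample_b, sep = "|")
  out
}

#' Pool abundances up to a target layer
#'
#' Collapses all layers beneath `target_layer` by summing each feature's
#' abundances over the samples under every unit of the target layer,
#' yielding one pooled sample per unit. Pooling happens after imputation
#' (no missing values allowed) and before log transformation, since sums
#' are taken on the abundance scale.
#'
#' @param table A `"marr_abundance"` object with no missing values.
#' @param target_layer Name of the layer whose units become the pooled
#'   samples.
#' @return A `"marr_abundance"` object whose layers run from the top
#'   layer down to `target_layer`.
#' @export
pool_lower_layers <- function(table, target_layer) {
  stopifnot(inherits(table, "marr_abundance"))
  if (!target_layer %in% table$layers) {
    stop_("unknown layer: ", target_layer)
  }
  if (anyNA(table$values)) {
    stop_("missing values present; impute before pooling")
  }
  keep <- table$layers[seq_len(match(target_layer, table$layers))]
  coords <- table$coordinates
  key <- do.call(paste, c(coords[keep], sep = "."))
  groups <- split(seq_len(ncol(table$values)), key)
  pooled <- vapply(groups, function(idx) {
    rowSums(table$values[, idx, drop = FALSE])
  }, numeric(nrow(table$values)))
  pooled <- matrix(pooled, nrow = nrow(table$values),
                   dimnames = list(rownames(table$values), names(groups)))
  new_coords <- do.call(rbind, lapply(names(groups), function(k) {
    coords[groups[[k]][1L], keep, drop = FALSE]
  }))
  new_coords <- cbind(data.frame(sample_id = names(groups),
                                 stringsAsFactors = FALSE),
                      new_coords)
  rownames(new_coords) <- NULL
  abundance_table(pooled, new_coords, layers = keep)
}
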