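#' Paired spatial multi-omics container
#'
#' Bundles two per-spot feature matrices measured on the same set of spots
#' (for example RNA counts and protein/ADT counts, or RNA and an LSI-reduced
#' chromatin matrix), the physical coordinates of the spots, and optional
#' ground-truth domain labels. All downstream functions
#' ([neighbor_graphs()], [gatfuse()], [run_ablation()]) take this object.
#'
#' @param x1 numeric matrix, spots x features, modality 1.
#' @param x2 numeric matrix, spots x features, modality 2; same rows as `x1`.
#' @param coords numeric matrix or data frame with two columns of physical
#'   coordinates (arbitrary length units), one row per spot.
#' @param spot_ids optional character vector of spot identifiers; defaults to
#'   rownames of `x1` or `spot_1..spot_N`.
#' @param labels optional vector (coerced to factor) of ground-truth spatial
#'   domains, used only for evaluation.
#' @return An object of class `spatial_omics_pair`: a list with elements
#'   `x1`, `x2`, `coords`, `spot_ids`, `labels`, `n_spots`.
#' @examples
#' sim <- simulate_spatial_pair(n_spots = 60, n_domains = 2, seed = 1)
#' pair <- spatial_omics_pair(sim$x1, sim$x2, sim$coords, labels = sim$labels)
#' pair
#' @export
spatial_omics_pair <- function(x1, x2, coords, spot_ids = NULL, labels = NULL) {
  x1 <- as.matrix(x1)
  x2 <- as.matrix(x2)
  coords <- as.matrix(coords)
  storage.mode(x1) <- "double"
  storage.mode(x2) <- "double"
  storage.mode(coords) <- "double"
  n <- nrow(x1)
  if (n < 2L)
    stop("a spatial_omics_pair needs at least 2 spots")
  if (nrow(x2) != n || nrow(coords) != n)
    stop("x1, x2 and coords must have the same number of rows (spots); got ",
         n, ", ", nrow(x2), ", ", nrow(coords))
  if (ncol(coords) != 2L)
    stop("coords must have exactly 2 columns")
  if (anyNA(x1) || anyNA(x2) || anyNA(coords) ||
      any(!is.finite(x1)) || any(!is.finite(x2)) || any(!is.finite(coords)))
    stop("x1, x2 and coords must be finite with no missing values")
  if (is.null(spot_ids)) {
    spot_ids <- rownames(x1)
    if (is.null(spot_ids)) spot_ids <- paste0("spot_", seq_len(n))
  }
  spot_ids <- as.character(spot_ids)
  if (length(spot_ids) != n)
    stop("spot_ids must have one entry per spot")
  if (!is.null(labels)) {
    labels <- as.factor(labels)
    if (length(labels) != n)
      stop("labels must have one entry per spot")
  }
  rownames(x1) <- rownames(x2) <- rownames(coords) <- spot_ids
  structure(
    list(x1 = x1, x2 = x2, coords = coords,
         spot_ids = spot_ids, labels = labels, n_spots = n),
    class = "spatial_omics_pair")
}

#' @method print spatial_omics_pair
#' @export
print.spatial_omics_pair <- function(x, ...) {
  cat("spatial_omics_pair:", x$n_spots, "spots\n")
  cat("  modality 1:", ncol(x$x1), "features\n")
  cat("  modality 2:", ncol(x$x2), "features\n")
  if (!is.null(x$labels))
    cat("  labels:", nlevels(x$labels), "domains\n")
  invisible(x)
}

#' Read a paired dataset from delimited text files
#'
#' Each matrix file is spots x features with a header row of feature names and
#' the spot identifier in the first column; the coordinate file has columns
#' spot id, x, y. This is the format written by [write_pair_csv()] and by the
#' synthetic-data preset exporter.
#'
#' @param x1_file,x2_file paths to the two feature matrices (CSV or TSV,
#'   inferred from the extension).
#' @param coords_file path to the coordinate table.
#' @param labels_file optional path to a two-column table (spot id, domain).
#' @return A [spatial_omics_pair()].
#' @export
read_pair_csv <- function(x1_file, x2_file, coords_file, labels_file = NULL) {
  x1 <- .read_matrix_txt(x1_file)
  x2 <- .read_matrix_txt(x2_file)
  co <- .read_matrix_txt(coords_file)
  if (!identical(rownames(x1), rownames(x2)) ||
      !identical(rownames(x1), rownames(co)))
    stop("spot identifiers disagree across input files")
  labels <- NULL
  if (!is.null(labels_file)) {
    lab <- utils::read.table(labels_file, header = TRUE, sep = .sep_for(labels_file),
                             row.names = 1, check.names = FALSE)
    labels <- factor(lab[rownames(x1), 1])
  }
  spatial_omics_pair(x1, x2, co[, 1:2, drop = FALSE],
                     spot_ids = rownames(x1), labels = labels)
}

#' Write a paired dataset as delimited text files
#'
#' @param pair a [spatial_omics_pair()].
#' @param dir output directory (created if missing); files `x1.csv`,
#'   `x2.csv`, `coords.csv` and, when labels exist, `labels.csv`.
#' @return Invisibly, the directory.
#' @export
write_pair_csv <- function(pair, dir) {
  stopifnot(inherits(pair, "spatial_omics_pair"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  .write_matrix_txt(pair$x1, file.path(dir, "x1.csv"))
  .write_matrix_txt(pair$x2, file.path(dir, "x2.csv"))
  co <- pair$coords
  colnames(co) <- c("x", "y")
  .write_matrix_txt(co, file.path(dir, "coords.csv"))
  if (!is.null(pair$labels)) {
    df <- data.frame(spot = pair$spot_ids, domain = pair$labels)
    utils::write.table(df, file.path(dir, "labels.csv"), sep = ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Read a sparse matrix-market matrix with sidecar name files
#'
#' Reads the conventional MTX triplet (`matrix.mtx` plus `barcodes.tsv` and
#' `features.tsv`) where the MTX stores features x spots, and returns a dense
#' spots x features matrix oriented for [spatial_omics_pair()].
#'
#' @param mtx_file path to the matrix-market file (features x spots).
#' @param barcodes_file one spot id per line.
#' @param features_file one feature name per line (first column used).
#' @return numeric matrix, spots x features, with dimnames.
#' @export
read_mtx_matrix <- function(mtx_file, barcodes_file, features_file) {
  m <- Matrix::readMM(mtx_file)
  barcodes <- utils::read.table(barcodes_file, header = FALSE,
                                stringsAsFactors = FALSE)[, 1]
  feats <- utils::read.table(features_file, header = FALSE,
                             stringsAsFactors = FALSE)[, 1]
  if (nrow(m) != length(feats) || ncol(m) != length(barcodes))
    stop("MTX dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecar files")
  out <- t(as.matrix(m))
  dimnames(out) <- list(barcodes, feats)
  out
}

.sep_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

.read_matrix_txt <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = .sep_for(path),
                          row.names = 1, check.names = FALSE)
  as.matrix(df)
}

.write_matrix_txt <- function(m, path) {
  df <- data.frame(spot = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = .sep_for(path),
                     row.names = FALSE, quote = FALSE)
}
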