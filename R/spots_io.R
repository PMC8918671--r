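#' Read a decoded-spot coordinate table
#'
#' Reads a plain-text CSV with one row per decoded mRNA molecule, carrying a
#' gene label and x/y coordinates in micrometers (the convention used by
#' decoded-spot tables from single-molecule spatially resolved
#' transcriptomics pipelines). Extra columns (e.g. a z coordinate or decoding
#' quality scores) are tolerated and ignored.
#'
#' @param path Path to a CSV file with a header row.
#' @param columns Named character vector (or list) mapping the canonical
#'   names `gene`, `x`, `y` to the header names used in the file. Defaults to
#'   `c(gene = "gene", x = "x", y = "y")`; partial overrides are allowed.
#' @param quiet Suppress the molecule/gene count message.
#' @return A `spot_table`: a `data.frame` with columns `gene` (character),
#'   `x` and `y` (numeric, micrometers), rows in file order.
#' @export
read_spots <- function(path, columns = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop_io("coordinate file not found: %s", path)
  map <- c(gene = "gene", x = "x", y = "y")
  if (!is.null(columns)) {
    columns <- unlist(columns)
    bad <- setdiff(names(columns), names(map))
    if (length(bad))
      stop_validation("unknown column mapping key(s): %s",
                      paste(bad, collapse = ", "))
    map[names(columns)] <- columns
  }
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character", data.table = FALSE,
                          showProgress = FALSE)
  for (canon in names(map)) {
    if (!map[[canon]] %in% names(dt))
      stop_format("column '%s' (mapped to '%s') not found in %s",
                  map[[canon]], canon, path)
  }
  out <- data.frame(gene = dt[[map[["gene"]]]],
                    x = suppressWarnings(as.numeric(dt[[map[["x"]]]])),
                    y = suppressWarnings(as.numeric(dt[[map[["y"]]]])),
                    stringsAsFactors = FALSE)
  for (col in c("x", "y")) {
    bad <- which(!is.finite(out[[col]]))
    if (length(bad))
      stop_format("non-numeric %s coordinate at data row %d of %s",
                  col, bad[1], path)
  }
  if (any(!nzchar(out$gene)))
    stop_format("empty gene label at data row %d of %s",
                which(!nzchar(out$gene))[1], path)
  out <- as_spot_table(out)
  if (!quiet)
    message(sprintf("read %d molecules, %d distinct genes from %s",
                    nrow(out), length(unique(out$gene)), path))
  out
}

#' Construct a spot table from vectors or a data frame
#'
#' @param x A data.frame with columns `gene`, `x`, `y`, or a character vector
#'   of gene labels.
#' @param xcoord,ycoord Numeric coordinate vectors (micrometers) when `x` is
#'   a gene-label vector.
#' @return A `spot_table` data.frame.
#' @export
as_spot_table <- function(x, xcoord = NULL, ycoord = NULL) {
  if (is.character(x)) {
    x <- data.frame(gene = x, x = as.numeric(xcoord), y = as.numeric(ycoord),
                    stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene", "x", "y") %in% names(x)))
  out <- data.frame(gene = as.character(x$gene), x = as.numeric(x$x),
                    y = as.numeric(x$y), stringsAsFactors = FALSE)
  if (nrow(out) && any(!is.finite(out$x) | !is.finite(out$y)))
    stop_validation("spot coordinates must be finite")
  class(out) <- c("spot_table", "data.frame")
  rownames(out) <- NULL
  out
}

#' Write a spot table as CSV
#'
#' Emits the same `gene,x,y` CSV layout [read_spots()] consumes, with enough
#' digits that a read/write round trip preserves coordinates.
#'
#' @param spots A `spot_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spots <- function(spots, path) {
  df <- data.frame(gene = spots$gene,
                   x = sprintf("%.10g", spots$x),
                   y = sprintf("%.10g", spots$y))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Read a cell-type signature matrix
#'
#' Reads reference expression signatures as CSV with cell types as rows and
#' gene names as columns; the first column holds the cell-type labels.
#' Values may be binary (marker panels) or normalized expression, and must
#' be finite and non-negative.
#'
#' @param path Path to the signature CSV.
#' @return A numeric matrix (cell types x genes) with row and column names
#'   in file order, of class `signature_matrix`.
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop_io("signature file not found: %s", path)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  header <- gsub('^"|"$', "", trimws(header))
  genes <- header[-1]
  if (anyDuplicated(genes))
    stop_format("duplicate gene column '%s' in %s",
                genes[duplicated(genes)][1], path)
  dt <- data.table::fread(path, sep = ",", header = TRUE,
                          colClasses = "character",
                          data.table = FALSE, showProgress = FALSE)
  celltypes <- dt[[1]]
  if (anyDuplicated(celltypes))
    stop_format("duplicate cell-type row '%s' in %s",
                celltypes[duplicated(celltypes)][1], path)
  values <- matrix(NA_real_, nrow(dt), length(genes),
                   dimnames = list(celltypes, genes))
  for (j in seq_along(genes)) {
    v <- suppressWarnings(as.numeric(dt[[j + 1L]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop_format("non-numeric value at row '%s', gene '%s' in %s",
                  celltypes[bad[1]], genes[j], path)
    values[, j] <- v
  }
  as_signature_matrix(values)
}

#' Construct a signature matrix
#'
#' @param values Numeric matrix, cell types as rows (rownames), genes as
#'   columns (colnames); finite, non-negative values.
#' @return A validated `signature_matrix`.
#' @export
as_signature_matrix <- function(values) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_validation("signature matrix needs cell-type rownames and gene colnames")
  if (anyDuplicated(rownames(values)))
    stop_validation("duplicate cell-type labels in signature matrix")
  if (anyDuplicated(colnames(values)))
    stop_validation("duplicate gene labels in signature matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop_validation("signature values must be finite and non-negative")
  class(values) <- c("signature_matrix", class(matrix()))
  values
}

#' Write a signature matrix as CSV
#'
#' @param sig A `signature_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signatures <- function(sig, path) {
  df <- data.frame(celltype = rownames(sig),
                   as.data.frame(unclass(sig), check.names = FALSE))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Restrict spots and signatures to their shared gene panel
#'
#' Guided cell typing only uses genes present in both the coordinate table
#' and the signature matrix. Both inputs are restricted to the intersection
#' of their gene labels (case-sensitive exact match), preserving the
#' signature's column order; dropped genes are reported.
#'
#' @param spots A `spot_table`.
#' @param sig A `signature_matrix`.
#' @param quiet Suppress the warning about dropped genes.
#' @return A list with elements `spots`, `sig`, and `report` (a list with
#'   character vectors `dropped_spots` and `dropped_sig`).
#' @export
align_genes <- function(spots, sig, quiet = FALSE) {
  spot_genes <- unique(spots$gene)
  sig_genes <- colnames(sig)
  shared <- intersect(sig_genes, spot_genes)
  if (nrow(spots) > 0 && length(shared) == 0)
    stop_validation("no genes shared between spot table and signature matrix")
  report <- list(dropped_spots = setdiff(spot_genes, shared),
                 dropped_sig = setdiff(sig_genes, shared))
  if (!quiet && (length(report$dropped_spots) || length(report$dropped_sig)))
    warning(sprintf(
      "align_genes: dropped %d gene(s) from spots, %d from signatures",
      length(report$dropped_spots), length(report$dropped_sig)),
      call. = FALSE)
  keep_cols <- shared[order(match(shared, sig_genes))]  # signature order
  sig2 <- sig[, keep_cols, drop = FALSE]
  class(sig2) <- class(sig)
  spots2 <- spots[spots$gene %in% shared, , drop = FALSE]
  rownames(spots2) <- NULL
  class(spots2) <- class(spots)
  list(spots = spots2, sig = sig2, report = report)
}

#' Write a cell-type map to disk
#'
#' Writes three artifacts sharing a common prefix: `<prefix>_labels.tsv`, the
#' integer label matrix (-1 = background, k >= 0 indexes the legend) as
#' tab-separated text; `<prefix>_legend.csv`, the legend with one hex color
#' per cell type; and `<prefix>_map.png`, a raster rendering with background
#' in neutral grey. [read_map()] on the prefix reconstructs the map exactly.
#'
#' @param map A `celltype_map` from [assign_celltypes()].
#' @param prefix Output path prefix.
#' @param palette Optional character vector of colors, at least one per
#'   legend entry; defaults to an HCL qualitative palette.
#' @param background_color Fill for background pixels in the PNG.
#' @return Named character vector of the files written, invisibly.
#' @export
write_map <- function(map, prefix, palette = NULL,
                      background_color = "#BEBEBE") {
  stopifnot(inherits(map, "celltype_map"))
  K <- length(map$legend)
  if (is.null(palette)) {
    palette <- grDevices::hcl.colors(max(K, 2L), "Dark 3")[seq_len(K)]
  } else if (length(palette) < K) {
    stop_validation("palette has %d colors but legend has %d cell types",
                    length(palette), K)
  }
  palette <- palette[seq_len(K)]

  labels_path <- paste0(prefix, "_labels.tsv")
  legend_path <- paste0(prefix, "_legend.csv")
  png_path <- paste0(prefix, "_map.png")

  data.table::fwrite(as.data.frame(map$labels), labels_path, sep = "\t",
                     col.names = FALSE)
  data.table::fwrite(data.frame(index = seq_len(K) - 1L,
                                celltype = map$legend,
                                color = toupper(palette)),
                     legend_path, quote = FALSE)

  rgb_cols <- grDevices::col2rgb(c(background_color, palette)) / 255
  idx <- map$labels + 2L  # background -1 -> column 1
  img <- array(0, dim = c(nrow(map$labels), ncol(map$labels), 3L))
  for (ch in 1:3) img[, , ch] <- matrix(rgb_cols[ch, idx], nrow(map$labels))
  png::writePNG(img, png_path)

  invisible(c(labels = labels_path, legend = legend_path, png = png_path))
}

#' Read a cell-type map written by [write_map()]
#'
#' @param prefix The prefix passed to [write_map()].
#' @param grid Optional `grid_spec` to attach.
#' @return A `celltype_map`.
#' @export
read_map <- function(prefix, grid = NULL) {
  labels_path <- paste0(prefix, "_labels.tsv")
  legend_path <- paste0(prefix, "_legend.csv")
  if (!file.exists(labels_path) || !file.exists(legend_path))
    stop_io("map artifacts not found for prefix %s", prefix)
  labels <- as.matrix(data.table::fread(labels_path, sep = "\t",
                                        header = FALSE, data.table = FALSE))
  dimnames(labels) <- NULL
  storage.mode(labels) <- "integer"
  legend <- data.table::fread(legend_path, data.table = FALSE)
  new_celltype_map(labels, legend$celltype, grid)
}

new_celltype_map <- function(labels, legend, grid = NULL) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (nrow(labels) && (min(labels) < -1L || max(labels) >= length(legend)))
    stop_validation("label matrix entries must lie in {-1, ..., K-1}")
  structure(list(labels = labels, legend = as.character(legend), grid = grid),
            class = "celltype_map")
}

#' @export
print.celltype_map <- function(x, ...) {
  n_bg <- sum(x$labels == -1L)
  cat(sprintf("celltype_map: %d x %d pixels, %d cell types, %.1f%% background\n",
              nrow(x$labels), ncol(x$labels), length(x$legend),
              100 * n_bg / max(1, length(x$labels))))
  invisible(x)
}

#' @export
print.spot_table <- function(x, ...) {
  cat(sprintf("spot_table: %d molecules, %d distinct genes\n",
              nrow(x), length(unique(x$gene))))
  if (nrow(x)) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
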