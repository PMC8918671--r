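#' Pearson correlation of one pixel's expression vector with a signature row
#'
#' Definitional Pearson correlation of two gene-expression vectors. If the
#' pixel vector has zero variance, no meaningful ranking against signatures
#' exists and `NA` is returned (treated as minus infinity in the argmax, so
#' such pixels are never assigned a cell type).
#'
#' @param expr Numeric vector, pixel expression across genes.
#' @param sig_row Numeric vector of the same length (>= 2), a signature row
#'   with nonzero variance.
#' @return A number in \[-1, 1\], or `NA` if `expr` has zero variance.
#' @export
correlate_pixel <- function(expr, sig_row) {
  if (length(expr) != length(sig_row))
    stop_validation("expression vector has length %d but signature row %d",
                    length(expr), length(sig_row))
  if (length(expr) < 2)
    stop_validation("correlation needs at least 2 genes")
  ex <- expr - mean(expr)
  sy <- sig_row - mean(sig_row)
  vx <- sum(ex^2); vy <- sum(sy^2)
  if (vy == 0) stop_validation("signature row has zero variance")
  if (vx == 0) return(NA_real_)
  sum(ex * sy) / sqrt(vx * vy)
}

#' Assign each pixel the best-correlating cell type
#'
#' Every pixel's gene expression vector (one entry per gene plane of the
#' density stack) is correlated against each cell-type signature, and the
#' pixel is labelled with the highest-correlating type. Pixels whose total
#' signal (sum over gene planes) falls below `threshold` are classified as
#' background (-1), as are pixels with an undefined correlation
#' (zero-variance expression vector). Ties are broken towards the lowest
#' signature row index, so the result is deterministic.
#'
#' @param stack A `density_stack` whose gene order equals the signature
#'   column order.
#' @param sig A `signature_matrix`; every row must have nonzero variance.
#' @param threshold Total-expression background cutoff (>= 0). Defaults to
#'   the threshold carried by `params` at stack creation time if supplied.
#' @param measure Correlation measure: `"pearson"` (default, as in the
#'   parent guided-mode algorithm) or `"cosine"`.
#' @return A `celltype_map`: integer label matrix (H x W, -1 = background),
#'   legend (signature row labels), and the stack's `grid_spec`.
#' @export
assign_celltypes <- function(stack, sig, threshold,
                             measure = c("pearson", "cosine")) {
  measure <- match.arg(measure)
  if (!identical(stack$genes, colnames(sig)))
    stop_validation("density stack gene order does not match signature columns")
  if (ncol(sig) < 2)
    stop_validation("typing requires at least 2 shared genes")
  sig_var <- apply(sig, 1, stats::var)
  if (any(sig_var == 0))
    stop_validation("signature row '%s' has zero variance",
                    rownames(sig)[which(sig_var == 0)[1]])
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0)
    stop_validation("threshold must be a single number >= 0")

  G <- dim(stack$values)[1]; H <- dim(stack$values)[2]; W <- dim(stack$values)[3]
  # pixels x genes; pixel linear index is column-major over the H x W matrix
  E <- t(matrix(stack$values, nrow = G))
  total <- rowSums(E)
  fg <- total >= threshold

  labels <- matrix(-1L, H, W)
  if (any(fg)) {
    Ef <- E[fg, , drop = FALSE]
    if (measure == "pearson") {
      cors <- suppressWarnings(stats::cor(t(Ef), t(unclass(sig))))
    } else {
      nrm_e <- sqrt(rowSums(Ef^2))
      nrm_s <- sqrt(rowSums(unclass(sig)^2))
      cors <- (Ef %*% t(unclass(sig))) / outer(nrm_e, nrm_s)
    }
    defined <- rowSums(is.finite(cors)) == ncol(cors)
    cors[!is.finite(cors)] <- -Inf
    best <- max.col(cors, ties.method = "first") - 1L
    best[!defined] <- -1L
    lab_vec <- rep(-1L, H * W)
    lab_vec[fg] <- best
    labels <- matrix(lab_vec, H, W)
  }
  new_celltype_map(labels, rownames(sig), stack$grid)
}

#' Quantify relative cell-type abundance in a rectangular view
#'
#' Counts classified pixels per cell type inside a view rectangle and
#' normalizes fractions over classified (non-background) pixels only, the
#' quantity shown as a per-view abundance barplot when panning or zooming
#' over a cell-type map.
#'
#' @param map A `celltype_map`.
#' @param view Optional view: a list with integer vectors `rows` and `cols`
#'   (1-based inclusive pixel ranges, e.g. `list(rows = 1:64, cols = 10:20)`),
#'   clipped to the map; `NULL` means the full map.
#' @return An `abundance_table` data.frame with columns `celltype`, `count`,
#'   `fraction`; the final row is `background` with fraction `NA`. Fractions
#'   sum to 1 when any pixel is classified, and are all 0 otherwise.
#' @export
quantify_abundance <- function(map, view = NULL) {
  H <- nrow(map$labels); W <- ncol(map$labels)
  if (is.null(view)) view <- list(rows = seq_len(H), cols = seq_len(W))
  rows <- intersect(view$rows, seq_len(H))
  cols <- intersect(view$cols, seq_len(W))
  if (!length(rows) || !length(cols))
    stop_validation("view rectangle is empty after clipping to the map")
  sub <- map$labels[rows, cols, drop = FALSE]
  K <- length(map$legend)
  counts <- tabulate(sub + 2L, nbins = K + 1L)  # slot 1 = background
  n_class <- sum(counts[-1])
  frac <- if (n_class > 0) counts[-1] / n_class else rep(0, K)
  out <- data.frame(celltype = c(map$legend, "background"),
                    count = c(counts[-1], counts[1]),
                    fraction = c(frac, NA_real_),
                    stringsAsFactors = FALSE)
  class(out) <- c("abundance_table", "data.frame")
  out
}

#' Write an abundance table as CSV
#'
#' @param ab An `abundance_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path) {
  df <- data.frame(celltype = ab$celltype, count = ab$count,
                   fraction = ifelse(is.na(ab$fraction), "",
                                     sprintf("%.10g", ab$fraction)))
  data.table::fwrite(df, path, quote = FALSE)
  invisible(path)
}

#' Analyze a small subsection at full-run resolution
#'
#' Runs the density estimation and cell typing on a rectangular crop of the
#' data, for interactive parameter optimization before committing to the
#' full image. The crop uses the same micrometers-per-pixel scale (hence the
#' same pixel-unit bandwidth) the full-image run would use, and its grid is
#' aligned to the full grid's pixel lattice, so pixels more than
#' `ceil(2 * bandwidth_px) + 1` pixels from the crop border reproduce the
#' full-run result exactly (the kernel is truncated at two bandwidths; the
#' extra pixel absorbs molecules just outside the crop that snap onto its
#' border pixel).
#'
#' @param spots The full `spot_table`.
#' @param center Numeric length-2, subsection center `(x, y)` in micrometers.
#' @param size Numeric length-1 or -2, subsection extent in micrometers
#'   (default 100 x 100).
#' @param params A `kde_params` (as for the full run).
#' @param sig A `signature_matrix` already aligned to the spot genes.
#' @param measure Correlation measure, see [assign_celltypes()].
#' @return List with `density` (a `density_stack` over the crop), `map` (a
#'   `celltype_map`), and `origin_px`, the 0-based (row, col) of the crop's
#'   pixel (0, 0) within the full-run grid.
#' @export
preview_subsection <- function(spots, center, size = c(100, 100), params, sig,
                               measure = "pearson") {
  if (length(size) == 1) size <- c(size, size)
  stopifnot(length(center) == 2, length(size) == 2)
  full <- make_grid(spots, params)
  x0 <- max(center[1] - size[1] / 2, min(spots$x))
  x1 <- min(center[1] + size[1] / 2, max(spots$x))
  y0 <- max(center[2] - size[2] / 2, min(spots$y))
  y1 <- min(center[2] + size[2] / 2, max(spots$y))
  keep <- spots$x >= x0 & spots$x <= x1 & spots$y >= y0 & spots$y <= y1
  if (x0 > x1 || y0 > y1 || !any(keep))
    stop_validation("subsection contains no molecules")
  crop <- spots[keep, , drop = FALSE]
  class(crop) <- class(spots)

  # snap the crop edges onto the full grid's pixel lattice so local pixel
  # (r, c) is full pixel (r + r0, c + c0)
  c0 <- min(max(round_half_away(full$scale * (x0 - full$x_min)), 0), full$width_px - 1L)
  c1 <- min(max(round_half_away(full$scale * (x1 - full$x_min)), 0), full$width_px - 1L)
  r0 <- min(max(round_half_away(full$scale * (y0 - full$y_min)), 0), full$height_px - 1L)
  r1 <- min(max(round_half_away(full$scale * (y1 - full$y_min)), 0), full$height_px - 1L)
  grid <- structure(list(x_min = full$x_min + c0 / full$scale,
                         y_min = full$y_min + r0 / full$scale,
                         scale = full$scale,
                         width_px = as.integer(c1 - c0 + 1L),
                         height_px = as.integer(r1 - r0 + 1L),
                         bandwidth_px = full$bandwidth_px),
                    class = "grid_spec")
  stack <- run_kde(crop, colnames(sig), params, grid)
  map <- assign_celltypes(stack, sig, params$threshold, measure = measure)
  list(density = stack, map = map, origin_px = c(row = r0, col = c0))
}
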