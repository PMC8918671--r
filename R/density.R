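#' KDE parameters
#'
#' The three parameters that govern the spatial model: the Gaussian kernel
#' bandwidth (standard deviation, micrometers; 2-25 um is a practical range
#' spanning dense assays with 20-30 molecules per cell at the low end and
#' sparse assays with 3-5 molecules per cell at the high end), the pixel
#' width of the output map, and the total-expression threshold below which a
#' pixel is treated as background. Bandwidth and threshold are
#' dataset-specific and have no defaults.
#'
#' @param bandwidth Gaussian sigma in micrometers, > 0.
#' @param width_px Output map width in pixels, integer >= 2.
#' @param threshold Total-expression background cutoff, >= 0, in units of
#'   effective molecules per pixel (each molecule contributes unit mass).
#' @return A `kde_params` list.
#' @export
kde_params <- function(bandwidth, width_px, threshold = 0) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 || !is.finite(bandwidth)
      || bandwidth <= 0)
    stop_validation("bandwidth must be a single positive number (micrometers)")
  if (!is.numeric(width_px) || length(width_px) != 1 || !is.finite(width_px)
      || width_px < 2 || width_px != floor(width_px))
    stop_validation("width_px must be an integer >= 2")
  if (!is.numeric(threshold) || length(threshold) != 1 || !is.finite(threshold)
      || threshold < 0)
    stop_validation("threshold must be a single number >= 0")
  structure(list(bandwidth = bandwidth, width_px = as.integer(width_px),
                 threshold = threshold),
            class = "kde_params")
}

#' Build the micrometer-to-pixel mapping for a spot table
#'
#' Coordinates are rescaled linearly so the horizontal data range fits the
#' requested pixel width; the height is chosen to cover the vertical spread
#' at the same scale (aspect ratio preserved), and the bandwidth is converted
#' to pixel units with the same factor.
#'
#' @param spots A non-empty `spot_table` whose x range is positive.
#' @param params A `kde_params`.
#' @return A `grid_spec` with fields `x_min`, `y_min` (um origin), `scale`
#'   (pixels per um), `width_px`, `height_px`, `bandwidth_px`.
#' @export
make_grid <- function(spots, params) {
  if (nrow(spots) == 0) stop_validation("cannot build a grid from zero spots")
  x_min <- min(spots$x); x_max <- max(spots$x)
  y_min <- min(spots$y); y_max <- max(spots$y)
  if (x_max - x_min <= 0)
    stop_validation("x coordinates have zero range; cannot rescale")
  scale <- params$width_px / (x_max - x_min)
  height_px <- max(1L, as.integer(ceiling(scale * (y_max - y_min))))
  structure(list(x_min = x_min, y_min = y_min, scale = scale,
                 width_px = params$width_px, height_px = height_px,
                 bandwidth_px = params$bandwidth * scale),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf(
    "grid_spec: %d x %d px, %.4g px/um, origin (%.4g, %.4g) um, sigma %.4g px\n",
    x$width_px, x$height_px, x$scale, x$x_min, x$y_min, x$bandwidth_px))
  invisible(x)
}

#' Snap molecule coordinates to their closest output pixel
#'
#' Each molecule maps to pixel `(round(scale * (y - y_min)),
#' round(scale * (x - x_min)))` with half-away-from-zero rounding, clamped to
#' the grid. Indices are 0-based: row 0 is the smallest y, column 0 the
#' smallest x.
#'
#' @param spots A `spot_table`.
#' @param grid A `grid_spec`.
#' @return Integer matrix with columns `row`, `col` (0-based), one row per
#'   molecule.
#' @export
snap_to_pixels <- function(spots, grid) {
  col <- round_half_away(grid$scale * (spots$x - grid$x_min))
  row <- round_half_away(grid$scale * (spots$y - grid$y_min))
  col <- pmin(pmax(col, 0), grid$width_px - 1L)
  row <- pmin(pmax(row, 0), grid$height_px - 1L)
  cbind(row = as.integer(row), col = as.integer(col))
}

#' Pre-computed truncated Gaussian mass patch
#'
#' A square matrix holding the Gaussian kernel evaluated at integer pixel
#' offsets, truncated at two bandwidths (radius `ceil(2 * sigma)`) and
#' renormalized to sum to one so every molecule deposits exactly one unit of
#' signal (making the expression threshold interpretable as effective
#' molecules per pixel).
#'
#' @param sigma_px Kernel standard deviation in pixel units, > 0.
#' @return A `gaussian_patch`: list with `mass` (P x P matrix, P = 2r + 1),
#'   `radius_px`, `sigma_px`.
#' @export
make_patch <- function(sigma_px) {
  if (!is.numeric(sigma_px) || length(sigma_px) != 1 || !is.finite(sigma_px)
      || sigma_px <= 0)
    stop_validation("sigma_px must be a single positive number")
  radius <- as.integer(ceiling(2 * sigma_px))
  d <- (-radius):radius
  v <- exp(-d^2 / (2 * sigma_px^2))
  mass <- outer(v, v)
  mass <- mass / sum(mass)
  structure(list(mass = mass, radius_px = radius, sigma_px = sigma_px),
            class = "gaussian_patch")
}

#' Fast per-gene kernel density estimation
#'
#' Computes one local-signal-strength pixel matrix per gene. Two heuristics
#' make this fast: molecules are snapped to their closest pixel so a single
#' pre-computed Gaussian mass patch serves every molecule, and the patch is
#' truncated at two bandwidths. Patch parts falling outside the grid are
#' cropped. The result is a pure sum, so it is deterministic and independent
#' of molecule order.
#'
#' @param spots A `spot_table`; every gene label must appear in `genes`.
#' @param genes Ordered character vector of gene labels defining the planes.
#' @param params A `kde_params`.
#' @param grid A `grid_spec`; defaults to `make_grid(spots, params)`.
#' @return A `density_stack`: list with `values` (G x H x W array), `genes`,
#'   `grid`, and `ops`, the exact number of patch-accumulation operations
#'   performed (`molecule count x P^2`, linear in the number of molecules).
#' @export
run_kde <- function(spots, genes, params, grid = NULL) {
  if (is.null(grid)) grid <- make_grid(spots, params)
  unknown <- setdiff(unique(spots$gene), genes)
  if (length(unknown))
    stop_validation("spot gene(s) not in the gene panel: %s (run align_genes)",
                    paste(utils::head(unknown, 5), collapse = ", "))
  patch <- make_patch(grid$bandwidth_px)
  H <- grid$height_px; W <- grid$width_px
  r <- patch$radius_px; P <- 2L * r + 1L
  G <- length(genes)
  values <- array(0, dim = c(G, H, W), dimnames = list(genes, NULL, NULL))

  if (nrow(spots)) {
    px <- snap_to_pixels(spots, grid)
    gi <- match(spots$gene, genes)
    # accumulate per-pixel molecule counts, then deposit count-weighted
    # patches on a zero-padded canvas: identical to per-molecule
    # accumulation, but order-invariant and far fewer R-level operations
    for (g in seq_len(G)) {
      sel <- gi == g
      if (!any(sel)) next
      counts <- matrix(0, H, W)
      tab <- table(px[sel, "row", drop = TRUE] * W + px[sel, "col", drop = TRUE])
      lin <- as.integer(names(tab))
      counts[cbind(lin %/% W + 1L, lin %% W + 1L)] <- as.numeric(tab)
      padded <- matrix(0, H + 2L * r, W + 2L * r)
      for (di in 0:(P - 1L)) for (dj in 0:(P - 1L)) {
        w <- patch$mass[di + 1L, dj + 1L]
        padded[(1L + di):(H + di), (1L + dj):(W + dj)] <-
          padded[(1L + di):(H + di), (1L + dj):(W + dj)] + w * counts
      }
      values[g, , ] <- padded[(r + 1L):(r + H), (r + 1L):(r + W)]
    }
  }

  structure(list(values = values, genes = genes, grid = grid,
                 ops = as.numeric(nrow(spots)) * P^2),
            class = "density_stack")
}

#' Exact naive kernel density estimation (verification oracle)
#'
#' The reference the fast estimator approximates: for every pixel, the sum of
#' untruncated Gaussians centered at the exact (continuous) molecule
#' positions, each molecule normalized to contribute total mass one over an
#' infinite pixel grid. No snapping, no truncation. Quadratic cost; intended
#' for small inputs only.
#'
#' @inheritParams run_kde
#' @return A `density_stack` (with `ops = NA`).
#' @export
naive_kde <- function(spots, genes, params, grid = NULL) {
  if (is.null(grid)) grid <- make_grid(spots, params)
  unknown <- setdiff(unique(spots$gene), genes)
  if (length(unknown))
    stop_validation("spot gene(s) not in the gene panel: %s",
                    paste(utils::head(unknown, 5), collapse = ", "))
  sigma <- grid$bandwidth_px
  H <- grid$height_px; W <- grid$width_px
  G <- length(genes)
  values <- array(0, dim = c(G, H, W), dimnames = list(genes, NULL, NULL))
  if (nrow(spots)) {
    cx <- grid$scale * (spots$x - grid$x_min)
    cy <- grid$scale * (spots$y - grid$y_min)
    gi <- match(spots$gene, genes)
    rows <- 0:(H - 1L); cols <- 0:(W - 1L)
    ext <- ceiling(8 * sigma)  # infinite-grid normalizer to machine precision
    for (m in seq_len(nrow(spots))) {
      ey <- exp(-(rows - cy[m])^2 / (2 * sigma^2))
      ex <- exp(-(cols - cx[m])^2 / (2 * sigma^2))
      ky <- round(cy[m]); kx <- round(cx[m])
      sy <- sum(exp(-((ky - ext):(ky + ext) - cy[m])^2 / (2 * sigma^2)))
      sx <- sum(exp(-((kx - ext):(kx + ext) - cx[m])^2 / (2 * sigma^2)))
      values[gi[m], , ] <- values[gi[m], , ] + outer(ey, ex) / (sy * sx)
    }
  }
  structure(list(values = values, genes = genes, grid = grid, ops = NA_real_),
            class = "density_stack")
}

#' Sum a density stack over genes
#'
#' The total local signal strength per pixel: the quantity inspected (as a
#' heatmap) when choosing the expression threshold, and the quantity the
#' threshold is applied to.
#'
#' @param stack A `density_stack`.
#' @return Numeric H x W matrix.
#' @export
density_sum <- function(stack) {
  apply(stack$values, c(2, 3), sum)
}

#' Write the gene-summed density matrix as TSV
#'
#' @param stack A `density_stack`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_sum <- function(stack, path) {
  m <- density_sum(stack)
  df <- as.data.frame(matrix(sprintf("%.10g", m), nrow(m)))
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.density_stack <- function(x, ...) {
  cat(sprintf("density_stack: %d genes x %d x %d px, total signal %.4g\n",
              dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              sum(x$values)))
  invisible(x)
}
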