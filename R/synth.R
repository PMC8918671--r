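#' Specify a synthetic tissue model
#'
#' A simple generative model of a single-molecule spatial transcriptomics
#' experiment with known ground truth: circular cells scattered over a
#' rectangular extent, each emitting a Poisson number of molecules whose
#' genes follow the cell type's signature row and whose positions are
#' isotropic Gaussian displacements from the cell center, plus uniformly
#' distributed extracellular noise molecules with uniformly random genes.
#'
#' @param cells Data frame with columns `x`, `y` (centers, um), `radius`
#'   (um) and `celltype` (1-based signature row index); or `NULL` to place
#'   `n_cells` cells uniformly at random.
#' @param sig A `signature_matrix`; every row must have positive sum.
#' @param depth Expected molecules per cell (Poisson mean), > 0.
#' @param noise_fraction Expected fraction of all molecules that are
#'   extracellular noise, in \[0, 1).
#' @param extent Numeric length-4 `c(x_min, x_max, y_min, y_max)` in um.
#' @param n_cells Number of cells when `cells` is `NULL`.
#' @param radius Cell radius in um when `cells` is `NULL`.
#' @param layout How cell types are arranged when `cells` is `NULL`:
#'   `"bands"` (default) assigns each cell the type of the horizontal band
#'   its center falls in, one band per signature row, emulating the layered
#'   spatial organization of tissues like the cortex; `"random"` assigns
#'   types independently and uniformly, a spatially unstructured null.
#' @return A `tissue_model` list.
#' @export
tissue_model <- function(cells = NULL, sig, depth = 20, noise_fraction = 0.1,
                         extent = c(0, 1000, 0, 1000), n_cells = 1000,
                         radius = 10, layout = c("bands", "random")) {
  layout <- match.arg(layout)
  if (any(rowSums(unclass(sig)) <= 0))
    stop_validation("signature row '%s' is all zero",
                    rownames(sig)[which(rowSums(unclass(sig)) <= 0)[1]])
  if (depth <= 0) stop_validation("depth must be > 0")
  if (noise_fraction < 0 || noise_fraction >= 1)
    stop_validation("noise_fraction must be in [0, 1)")
  if (!is.null(cells)) {
    stopifnot(all(c("x", "y", "radius", "celltype") %in% names(cells)))
    if (any(cells$x < extent[1] | cells$x > extent[2] |
            cells$y < extent[3] | cells$y > extent[4]))
      stop_validation("cell centers must lie inside the extent")
    if (any(cells$celltype < 1 | cells$celltype > nrow(sig)))
      stop_validation("cell type index out of signature range")
  }
  structure(list(cells = cells, sig = sig, depth = depth,
                 noise_fraction = noise_fraction, extent = extent,
                 n_cells = n_cells, radius = radius, layout = layout),
            class = "tissue_model")
}

#' Simulate a decoded-spot table with known ground truth
#'
#' Draws molecules from a [tissue_model()]: per cell a Poisson(`depth`)
#' molecule count, genes sampled with probability proportional to the cell
#' type's signature row, positions displaced from the center by an isotropic
#' Gaussian with standard deviation `radius / 2` and clipped to the extent.
#' Noise molecules (uniform position, uniform gene over the panel) are added
#' so their expected share of all molecules equals `noise_fraction`.
#' Deterministic given `seed`.
#'
#' @param model A `tissue_model`.
#' @param seed Integer RNG seed.
#' @return List with `spots` (a `spot_table`), `cells` (the realized cell
#'   table), and `is_noise` (logical per spot).
#' @export
simulate_spots <- function(model, seed = 1L) {
  set.seed(as.integer(seed))
  ext <- model$extent
  cells <- model$cells
  if (is.null(cells)) {
    K <- nrow(model$sig)
    x <- stats::runif(model$n_cells, ext[1], ext[2])
    y <- stats::runif(model$n_cells, ext[3], ext[4])
    ct <- if (model$layout == "bands") {
      pmin(K, floor(K * (y - ext[3]) / (ext[4] - ext[3])) + 1L)
    } else {
      sample.int(K, model$n_cells, replace = TRUE)
    }
    cells <- data.frame(x = x, y = y, radius = rep(model$radius, model$n_cells),
                        celltype = as.integer(ct))
  }
  genes <- colnames(model$sig)
  n_per_cell <- stats::rpois(nrow(cells), model$depth)
  total <- sum(n_per_cell)
  ct <- rep(cells$celltype, n_per_cell)
  cx <- rep(cells$x, n_per_cell)
  cy <- rep(cells$y, n_per_cell)
  sd_pos <- rep(cells$radius, n_per_cell) / 2

  gene_idx <- integer(total)
  for (k in seq_len(nrow(model$sig))) {
    sel <- which(ct == k)
    if (length(sel))
      gene_idx[sel] <- sample.int(length(genes), length(sel), replace = TRUE,
                                  prob = model$sig[k, ])
  }
  x <- pmin(pmax(cx + stats::rnorm(total, 0, sd_pos), ext[1]), ext[2])
  y <- pmin(pmax(cy + stats::rnorm(total, 0, sd_pos), ext[3]), ext[4])

  nf <- model$noise_fraction
  n_noise <- if (nf > 0) stats::rpois(1, total * nf / (1 - nf)) else 0L
  if (n_noise > 0) {
    x <- c(x, stats::runif(n_noise, ext[1], ext[2]))
    y <- c(y, stats::runif(n_noise, ext[3], ext[4]))
    gene_idx <- c(gene_idx, sample.int(length(genes), n_noise, replace = TRUE))
  }
  spots <- as_spot_table(genes[gene_idx], x, y)
  list(spots = spots, cells = cells,
       is_noise = c(rep(FALSE, total), rep(TRUE, n_noise)))
}

#' Rasterize a tissue model's ground truth onto a grid
#'
#' For each pixel center, the true cell type is that of the nearest cell
#' whose radius covers the pixel center; pixels covered by no cell are
#' background (-1).
#'
#' @param cells Realized cell table from [simulate_spots()].
#' @param sig The `signature_matrix` used in the model (for the legend).
#' @param grid A `grid_spec`.
#' @return A `celltype_map` of ground-truth labels.
#' @export
ground_truth_map <- function(cells, sig, grid) {
  H <- grid$height_px; W <- grid$width_px
  px <- grid$x_min + (0:(W - 1L)) / grid$scale
  py <- grid$y_min + (0:(H - 1L)) / grid$scale
  labels <- matrix(-1L, H, W)
  best_d2 <- matrix(Inf, H, W)
  for (i in seq_len(nrow(cells))) {
    r <- cells$radius[i]
    cset <- which(abs(px - cells$x[i]) <= r)
    rset <- which(abs(py - cells$y[i]) <= r)
    if (!length(cset) || !length(rset)) next
    d2 <- outer((py[rset] - cells$y[i])^2, (px[cset] - cells$x[i])^2, "+")
    hit <- d2 <= r^2 & d2 < best_d2[rset, cset, drop = FALSE]
    if (any(hit)) {
      sub_lab <- labels[rset, cset, drop = FALSE]
      sub_d2 <- best_d2[rset, cset, drop = FALSE]
      sub_lab[hit] <- as.integer(cells$celltype[i] - 1L)
      sub_d2[hit] <- d2[hit]
      labels[rset, cset] <- sub_lab
      best_d2[rset, cset] <- sub_d2
    }
  }
  new_celltype_map(labels, rownames(sig), grid)
}

#' Scale a dataset down or up by replication with pixel shifts
#'
#' Benchmark-style dataset scaling: `0.5` draws a seeded uniform sample of
#' `floor(N/2)` molecules without replacement; `2` appends a copy of the
#' dataset shifted by +1 um along both axes; `3` appends to the 2x dataset a
#' copy of the original shifted by -1 um along both axes; `5` appends four
#' copies shifted by +1, +2, +3 and +4 um along both axes. Gene labels are
#' preserved, so the gene marginal distribution is invariant under the
#' upscaling constructions.
#'
#' @param spots A non-empty `spot_table`.
#' @param factor One of 0.5, 2, 3, 5.
#' @param seed Integer seed (used only for `factor = 0.5`).
#' @return A `spot_table` with `floor(N/2)`, `2N`, `3N` or `5N` rows.
#' @export
scale_dataset <- function(spots, factor, seed = 1L) {
  if (nrow(spots) == 0) stop_validation("cannot scale an empty spot table")
  shift <- function(d, s) {
    d$x <- d$x + s; d$y <- d$y + s; d
  }
  out <- if (isTRUE(all.equal(factor, 0.5))) {
    set.seed(as.integer(seed))
    spots[sort(sample.int(nrow(spots), nrow(spots) %/% 2L)), , drop = FALSE]
  } else if (isTRUE(all.equal(factor, 2))) {
    rbind(spots, shift(spots, 1))
  } else if (isTRUE(all.equal(factor, 3))) {
    rbind(spots, shift(spots, 1), shift(spots, -1))
  } else if (isTRUE(all.equal(factor, 5))) {
    rbind(spots, shift(spots, 1), shift(spots, 2), shift(spots, 3),
          shift(spots, 4))
  } else {
    stop_validation("unsupported scaling factor %s (use 0.5, 2, 3 or 5)",
                    format(factor))
  }
  rownames(out) <- NULL
  class(out) <- c("spot_table", "data.frame")
  out
}
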