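# Shared fixture builders; everything is generated in code at test time.

# Block-binary signature matrix: K cell types, each marked by a disjoint
# block of markers_per_type genes.
block_signatures <- function(K = 5, markers_per_type = 4) {
  G <- K * markers_per_type
  m <- matrix(0, K, G,
              dimnames = list(paste0("type", seq_len(K)),
                              paste0("g", seq_len(G))))
  for (k in seq_len(K))
    m[k, ((k - 1) * markers_per_type + 1):(k * markers_per_type)] <- 1
  as_signature_matrix(m)
}

# Write a gene,x,y CSV and return its path.
write_spots_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(c("gene,x,y", lines), path)
  path
}

# Uniform random single-gene spot table with the extent pinned by two
# molecules at opposite corners; remaining molecules keep `margin` um from
# every border.
pinned_uniform_spots <- function(n, extent = 64, margin = 7, genes = "A",
                                 seed = 42) {
  set.seed(seed)
  x <- runif(n, margin, extent - margin)
  y <- runif(n, margin, extent - margin)
  x[1] <- 0; y[1] <- 0; x[2] <- extent; y[2] <- extent
  as_spot_table(sample(genes, n, replace = TRUE), x, y)
}

# Definitional per-pixel Pearson + argmax assigner used as an independent
# oracle against the vectorized implementation.
assign_by_loop <- function(stack, sig, threshold) {
  G <- dim(stack$values)[1]; H <- dim(stack$values)[2]; W <- dim(stack$values)[3]
  labels <- matrix(-1L, H, W)
  for (r in seq_len(H)) for (c in seq_len(W)) {
    v <- stack$values[, r, c]
    if (sum(v) < threshold) next
    if (stats::var(v) == 0) next
    cors <- vapply(seq_len(nrow(sig)), function(k) {
      a <- v - mean(v); b <- sig[k, ] - mean(sig[k, ])
      sum(a * b) / sqrt(sum(a^2) * sum(b^2))
    }, numeric(1))
    labels[r, c] <- which.max(cors) - 1L  # which.max takes the first maximum
  }
  labels
}

# Density stack wrapper around a raw G x H x W array.
stack_from_array <- function(values, genes, grid = NULL) {
  structure(list(values = values, genes = genes, grid = grid, ops = NA_real_),
            class = "density_stack")
}

demo_grid <- function(H, W) {
  structure(list(x_min = 0, y_min = 0, scale = 1, width_px = as.integer(W),
                 height_px = as.integer(H), bandwidth_px = 1),
            class = "grid_spec")
}
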