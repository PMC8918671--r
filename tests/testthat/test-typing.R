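test_that("correlate_pixel is definitional Pearson with its invariances", {
  s <- c(1, 3, 2, 5)
  expect_equal(correlate_pixel(2 * s + 3, s), 1)       # positive affine
  expect_equal(correlate_pixel(-s + 10, s), -1)
  expect_equal(correlate_pixel(c(1, 0, 0), c(0, 1, 0)), -0.5)  # hand-computed
  expect_true(is.na(correlate_pixel(c(2, 2, 2), s[1:3])))      # zero variance
  expect_error(correlate_pixel(c(1, 2), c(1, 2, 3)),
               class = "spottype_validation_error")
  expect_error(correlate_pixel(c(1, 2, 3), c(4, 4, 4)),
               class = "spottype_validation_error")
})

test_that("assign_celltypes picks the best-correlating type above threshold", {
  sig <- block_signatures(3, 2)  # 3 types x 6 genes
  vals <- array(0, dim = c(6, 2, 2), dimnames = list(colnames(sig), NULL, NULL))
  vals[, 1, 1] <- 3 * sig[3, ]            # proportional to type3
  vals[, 1, 2] <- c(1, 1, 1, 1, 0, 0)     # equal correlation to types 1 and 2
  vals[, 2, 1] <- 0.5 * sig[1, ]          # total 1.0, below threshold 1.5
  vals[, 2, 2] <- c(2, 2, 2, 2, 2, 2)     # zero variance: never assigned
  stack <- stack_from_array(vals, colnames(sig), demo_grid(2, 2))
  map <- assign_celltypes(stack, sig, threshold = 1.5)
  expect_equal(map$labels[1, 1], 2L)   # type3 has index 2
  expect_equal(map$labels[1, 2], 0L)   # tie broken towards the lowest index
  expect_equal(map$labels[2, 1], -1L)  # below threshold
  expect_equal(map$labels[2, 2], -1L)  # undefined correlation
  expect_equal(map$legend, rownames(sig))

  # the tie really is a tie
  expect_equal(correlate_pixel(vals[, 1, 2], sig[1, ]),
               correlate_pixel(vals[, 1, 2], sig[2, ]))

  # gene-order mismatch and zero-variance signature rows are errors
  stack2 <- stack_from_array(vals[6:1, , ], rev(colnames(sig)), demo_grid(2, 2))
  expect_error(assign_celltypes(stack2, sig, 0),
               class = "spottype_validation_error")
  badsig <- as_signature_matrix(
    rbind(sig, typeflat = rep(1, 6))[, , drop = FALSE])
  expect_error(assign_celltypes(stack, badsig, 0), "typeflat",
               class = "spottype_validation_error")
})

test_that("vectorized assigner matches the definitional per-pixel oracle", {
  set.seed(31)
  for (rep in 1:4) {
    K <- sample(2:6, 1); G <- sample(4:9, 1)
    sig <- matrix(rexp(K * G), K, G,
                  dimnames = list(paste0("t", 1:K), paste0("g", 1:G)))
    sig <- as_signature_matrix(sig)
    vals <- array(rexp(G * 8 * 8), dim = c(G, 8, 8),
                  dimnames = list(colnames(sig), NULL, NULL))
    # sprinkle degenerate pixels
    vals[, 1, 1] <- 0
    vals[, 2, 2] <- 1
    stack <- stack_from_array(vals, colnames(sig), demo_grid(8, 8))
    th <- stats::median(apply(vals, c(2, 3), sum))
    map <- assign_celltypes(stack, sig, th)
    expect_identical(map$labels, assign_by_loop(stack, sig, th))
  }
})

test_that("raising the threshold only grows background, never flips labels", {
  sig <- block_signatures(4, 3)
  sim <- simulate_spots(tissue_model(sig = sig, n_cells = 60, depth = 15,
                                     noise_fraction = 0.1,
                                     extent = c(0, 200, 0, 200)), seed = 4)
  params <- kde_params(10, 80, 0)
  stack <- run_kde(sim$spots, colnames(sig), params)
  prev <- assign_celltypes(stack, sig, 0)
  for (th in c(0.05, 0.1, 0.2, 0.5, 1)) {
    cur <- assign_celltypes(stack, sig, th)
    expect_gte(sum(cur$labels == -1L), sum(prev$labels == -1L))
    still_fg <- cur$labels != -1L
    expect_identical(cur$labels[still_fg], prev$labels[still_fg])
    prev <- cur
  }
})

test_that("foreground labels are invariant to positive rescaling of the stack", {
  sig <- block_signatures(3, 3)
  set.seed(12)
  vals <- array(rexp(9 * 6 * 6), dim = c(9, 6, 6),
                dimnames = list(colnames(sig), NULL, NULL))
  stack <- stack_from_array(vals, colnames(sig), demo_grid(6, 6))
  scaled <- stack_from_array(vals * 7.3, colnames(sig), demo_grid(6, 6))
  m1 <- assign_celltypes(stack, sig, 0)
  m2 <- assign_celltypes(scaled, sig, 0)
  expect_identical(m1$labels, m2$labels)
})

test_that("quantify_abundance counts classified pixels per view", {
  labels <- matrix(c(0L, 1L, 0L, -1L), 2, 2, byrow = TRUE)
  map <- spottype:::new_celltype_map(labels, c("t1", "t2"), demo_grid(2, 2))
  ab <- quantify_abundance(map)
  expect_equal(ab$count, c(2, 1, 1))
  expect_equal(ab$fraction[1:2], c(2 / 3, 1 / 3))
  expect_equal(sum(ab$count), 4)  # counts sum to the ROI pixel count

  # single classified pixel
  one <- quantify_abundance(map, list(rows = 2, cols = 1))
  expect_equal(one$fraction[one$celltype == "t1"], 1)

  # all-background view
  bg <- quantify_abundance(map, list(rows = 2, cols = 2))
  expect_equal(bg$fraction[1:2], c(0, 0))
  expect_equal(bg$count, c(0, 0, 1))

  expect_error(quantify_abundance(map, list(rows = 5:6, cols = 1)),
               class = "spottype_validation_error")
})

test_that("abundance fractions sum to one whenever a pixel is classified", {
  set.seed(77)
  for (rep in 1:5) {
    labels <- matrix(sample(c(-1L, 0L, 1L, 2L), 30, TRUE), 5, 6)
    map <- spottype:::new_celltype_map(labels, paste0("t", 1:3), demo_grid(5, 6))
    view <- list(rows = sample.int(5, 3), cols = sample.int(6, 4))
    ab <- quantify_abundance(map, view)
    n_class <- sum(ab$count[1:3])
    if (n_class > 0) expect_equal(sum(ab$fraction[1:3]), 1)
    expect_equal(sum(ab$count), 12)
  }
})

test_that("a full-extent preview reproduces the full-image pipeline", {
  sig <- block_signatures(3, 3)
  sim <- simulate_spots(tissue_model(sig = sig, n_cells = 40, depth = 15,
                                     noise_fraction = 0.05,
                                     extent = c(0, 150, 0, 150)), seed = 6)
  params <- kde_params(8, 60, 0.1)
  full_stack <- run_kde(sim$spots, colnames(sig), params)
  full_map <- assign_celltypes(full_stack, sig, params$threshold)
  ext <- c(range(sim$spots$x), range(sim$spots$y))
  pv <- preview_subsection(sim$spots, center = c(mean(ext[1:2]), mean(ext[3:4])),
                           size = c(diff(ext[1:2]), diff(ext[3:4])),
                           params = params, sig = sig)
  expect_equal(pv$density$values, full_stack$values)
  expect_identical(pv$map$labels, full_map$labels)
  expect_equal(unname(pv$origin_px), c(0, 0))
})

test_that("preview interior pixels match the full run exactly", {
  sig <- block_signatures(4, 3)
  sim <- simulate_spots(tissue_model(sig = sig, n_cells = 150, depth = 20,
                                     noise_fraction = 0.1,
                                     extent = c(0, 400, 0, 400)), seed = 21)
  params <- kde_params(10, 160, 0.15)
  full_stack <- run_kde(sim$spots, colnames(sig), params)
  full_map <- assign_celltypes(full_stack, sig, params$threshold)
  g <- full_stack$grid
  pv <- preview_subsection(sim$spots, center = c(200, 200), size = c(120, 120),
                           params = params, sig = sig)
  # molecules just outside the crop snap to its border pixel, so the
  # exactly-reproduced interior starts one pixel beyond the patch radius
  r <- ceiling(2 * g$bandwidth_px) + 1
  H <- pv$map$grid$height_px; W <- pv$map$grid$width_px
  rows <- (r + 1):(H - r); cols <- (r + 1):(W - r)
  expect_identical(pv$map$labels[rows, cols],
                   full_map$labels[rows + pv$origin_px[["row"]],
                                   cols + pv$origin_px[["col"]]])
  expect_equal(pv$density$values[, rows, cols],
               full_stack$values[, rows + pv$origin_px[["row"]],
                                 cols + pv$origin_px[["col"]]])

  expect_error(preview_subsection(sim$spots, center = c(-500, -500),
                                  size = 10, params = params, sig = sig),
               class = "spottype_validation_error")
})
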