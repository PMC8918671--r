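#' Assemble a pipeline run configuration
#'
#' Collects everything one full analysis needs: input paths, the three model
#' parameters (map pixel width, kernel bandwidth in micrometers, total
#' expression threshold — bandwidth and threshold are dataset-specific and
#' therefore mandatory), the correlation measure, an optional preview
#' rectangle, and the output prefix.
#'
#' @param coords Path to the molecule coordinate CSV.
#' @param signatures Path to the signature CSV.
#' @param width_px Output map pixel width.
#' @param bandwidth Kernel bandwidth, micrometers.
#' @param threshold Total-expression background cutoff.
#' @param measure `"pearson"` or `"cosine"`.
#' @param out Output path prefix (directories are created as needed).
#' @param preview_center Optional numeric length-2 `(x, y)` in um.
#' @param preview_size Numeric length-1 or -2 preview extent in um.
#' @param columns Optional column mapping for [read_spots()].
#' @return A `run_config` list.
#' @export
run_config <- function(coords, signatures, width_px, bandwidth, threshold,
                       measure = "pearson", out = "spottype_out",
                       preview_center = NULL, preview_size = c(100, 100),
                       columns = NULL) {
  params <- kde_params(bandwidth, width_px, threshold)
  measure <- match.arg(measure, c("pearson", "cosine"))
  structure(list(coords = coords, signatures = signatures, params = params,
                 measure = measure, out = out,
                 preview_center = preview_center,
                 preview_size = preview_size, columns = columns),
            class = "run_config")
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("[%s] %s", stage, conditionMessage(e)),
                        class = c("spottype_stage_error", class(e))))
  })
}

config_as_list <- function(config) {
  list(coords = config$coords, signatures = config$signatures,
       width_px = config$params$width_px,
       bandwidth = config$params$bandwidth,
       threshold = config$params$threshold,
       measure = config$measure, out = config$out,
       preview_center = config$preview_center,
       preview_size = config$preview_size)
}

#' Run the full analysis pipeline
#'
#' Executes read, gene alignment, grid construction, per-gene density
#' estimation, cell typing and abundance quantification, and writes all
#' artifacts: label matrix TSV, legend CSV, map PNG, gene-summed density
#' TSV, abundance CSV and a sidecar YAML recording every parameter. The
#' pipeline contains no randomness, so identical configs and inputs yield
#' byte-identical outputs. On error, the message is prefixed with the name
#' of the failing stage.
#'
#' @param config A `run_config`.
#' @param quiet Suppress the printed summary.
#' @return Invisibly, a summary list: molecule counts, genes used,
#'   foreground fraction, the abundance table, and the paths written.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  spots <- with_stage("read_spots",
                      read_spots(config$coords, config$columns, quiet = TRUE))
  sig <- with_stage("read_signatures", read_signatures(config$signatures))
  aligned <- with_stage("align_genes", align_genes(spots, sig, quiet = quiet))
  grid <- with_stage("make_grid", make_grid(aligned$spots, config$params))
  stack <- with_stage("run_kde",
                      run_kde(aligned$spots, colnames(aligned$sig),
                              config$params, grid))
  map <- with_stage("assign_celltypes",
                    assign_celltypes(stack, aligned$sig,
                                     config$params$threshold,
                                     measure = config$measure))
  abundance <- with_stage("quantify_abundance", quantify_abundance(map))

  out_dir <- dirname(config$out)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- with_stage("write_outputs", {
    f <- write_map(map, config$out)
    f["density"] <- write_density_sum(stack, paste0(config$out, "_density.tsv"))
    f["abundance"] <- write_abundance(abundance,
                                      paste0(config$out, "_abundance.csv"))
    f["config"] <- paste0(config$out, "_config.yaml")
    yaml::write_yaml(config_as_list(config), f[["config"]])
    f
  })

  fg_fraction <- mean(map$labels != -1L)
  summary <- list(n_molecules = nrow(spots),
                  n_molecules_used = nrow(aligned$spots),
                  genes_used = colnames(aligned$sig),
                  dropped = aligned$report,
                  grid = grid,
                  foreground_fraction = fg_fraction,
                  abundance = abundance,
                  files = files)
  if (!quiet) {
    message(sprintf("molecules: %d (%d on shared gene panel of %d genes)",
                    summary$n_molecules, summary$n_molecules_used,
                    length(summary$genes_used)))
    message(sprintf("grid: %d x %d px; foreground fraction: %.3f",
                    grid$width_px, grid$height_px, fg_fraction))
    for (i in seq_len(nrow(abundance)))
      message(sprintf("  %-20s %8d px  %s", abundance$celltype[i],
                      abundance$count[i],
                      ifelse(is.na(abundance$fraction[i]), "",
                             sprintf("%5.1f%%", 100 * abundance$fraction[i]))))
  }
  invisible(summary)
}

#' Run a subsection preview from a configuration
#'
#' Crops the data to the configured preview rectangle, runs the density
#' estimation and typing at full-run resolution on the crop, and writes the
#' subsection density-sum TSV, map artifacts and a sidecar YAML config so a
#' full run can reuse the same parameters.
#'
#' @param config A `run_config` with `preview_center` set.
#' @param quiet Suppress messages.
#' @return Invisibly, the [preview_subsection()] result plus `files`.
#' @export
run_preview <- function(config, quiet = FALSE) {
  if (is.null(config$preview_center))
    stop_validation("preview requires a center point (preview_center)")
  spots <- with_stage("read_spots",
                      read_spots(config$coords, config$columns, quiet = TRUE))
  sig <- with_stage("read_signatures", read_signatures(config$signatures))
  aligned <- with_stage("align_genes", align_genes(spots, sig, quiet = quiet))
  pv <- with_stage("preview_subsection",
                   preview_subsection(aligned$spots, config$preview_center,
                                      config$preview_size, config$params,
                                      aligned$sig, measure = config$measure))
  prefix <- paste0(config$out, "_preview")
  out_dir <- dirname(prefix)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- with_stage("write_outputs", {
    f <- write_map(pv$map, prefix)
    f["density"] <- write_density_sum(pv$density, paste0(prefix, "_density.tsv"))
    f["config"] <- paste0(prefix, "_config.yaml")
    yaml::write_yaml(config_as_list(config), f[["config"]])
    f
  })
  if (!quiet)
    message(sprintf("preview: %d x %d px, foreground fraction %.3f",
                    pv$map$grid$width_px, pv$map$grid$height_px,
                    mean(pv$map$labels != -1L)))
  invisible(c(pv, list(files = files)))
}

#' Load a run configuration from a YAML file
#'
#' Reads a flat key-value YAML (as emitted as the pipeline's sidecar config)
#' into a [run_config()]. Entries in `overrides` take precedence, mirroring
#' command-line flags overriding a config file.
#'
#' @param path Path to the YAML file.
#' @param overrides Named list of fields to override.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  run_config(coords = vals$coords, signatures = vals$signatures,
             width_px = vals$width_px, bandwidth = vals$bandwidth,
             threshold = vals$threshold,
             measure = if (is.null(vals$measure)) "pearson" else vals$measure,
             out = if (is.null(vals$out)) "spottype_out" else vals$out,
             preview_center = unlist(vals$preview_center),
             preview_size = if (is.null(vals$preview_size)) c(100, 100)
                            else unlist(vals$preview_size))
}
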