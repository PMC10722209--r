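default_config <- function() {
  list(
    preprocess = list(sigma_mm = 0, resample_mm = NULL, connectivity = 6,
                      largest_component = TRUE),
    hull = list(method = "multiplanar"),
    chambers = list(enabled = FALSE, seeds = NULL, tol = 1e-6, omega = 1.9),
    thickness = list(method = "coupled_pde", tol = 1e-6, max_iter = NULL),
    variance = list(radius_px = 3),
    stats = list(threshold_mm = 7.2, alpha = 0.05)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a pipeline configuration
#'
#' YAML file or a plain list; missing keys fall back to package defaults
#' (no resampling, no smoothing, multiplanar hull, coupled-PDE thickness,
#' 3-pixel variance radius, 7.2 mm threshold).
#'
#' @param config path to a YAML file, a list, or `NULL` for the defaults.
#' @return configuration list.
#' @export
read_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  merge_config(base, config)
}

#' Run the full wall-thickness pipeline
#'
#' Preprocess (optional resampling/smoothing, largest-component cleanup) ->
#' multi-planar hull closure and surface labelling -> optional chamber
#' delineation -> thickness -> local-variance map -> summary statistics.
#' Every intermediate is written to the run directory as NIfTI (plus JSON
#' reports and the resolved configuration), and the pipeline is fully
#' deterministic: the same configuration and inputs give bit-identical
#' outputs.
#'
#' @param tissue input tissue segmentation: a binary `awt_volume` or a
#'   NIfTI path.
#' @param out_dir run directory (created).
#' @param config see [read_config()].
#' @param region optional region-of-interest mask (volume or path) summarised
#'   separately.
#' @return Invisibly, a list with the key results (`boundaries`,
#'   `thickness`, `variance`, `summary`, `paths`).
#' @export
run_pipeline <- function(tissue, out_dir, config = NULL, region = NULL) {
  cfg <- read_config(config)
  if (is.character(tissue)) tissue <- read_volume(tissue)
  if (is.character(region)) region <- read_volume(region)
  stopifnot_binary(tissue, "tissue")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(yaml::as.yaml(cfg), file.path(out_dir, "config.yaml"))

  pp <- tissue
  if (!is.null(cfg$preprocess$resample_mm))
    pp <- resample_mask(pp, cfg$preprocess$resample_mm)
  if (cfg$preprocess$sigma_mm > 0)
    pp <- smooth_mask(pp, cfg$preprocess$sigma_mm)
  if (isTRUE(cfg$preprocess$largest_component))
    pp <- largest_component(pp, cfg$preprocess$connectivity)
  write_volume(pp, file.path(out_dir, "tissue.nii"))

  hull <- multiplanar_convex_hull(pp, method = cfg$hull$method)
  b <- label_boundaries(pp, hull)
  write_boundaries(b, file.path(out_dir, "boundaries.nii"))

  chambers <- NULL
  if (isTRUE(cfg$chambers$enabled)) {
    sd <- cfg$chambers$seeds
    if (is.null(sd)) stop("chamber delineation enabled but no seeds given")
    chambers <- delineate_chambers(pp, sd[[1]], sd[[2]], tol = cfg$chambers$tol,
                                   omega = cfg$chambers$omega)
    write_volume(chambers$labels, file.path(out_dir, "chambers.nii"))
  }

  th <- switch(cfg$thickness$method,
               coupled_pde = thickness_coupled_pde(b, tol = cfg$thickness$tol,
                                                   max_iter = cfg$thickness$max_iter),
               laplace_streamline = thickness_laplace_streamline(b, tol = cfg$thickness$tol),
               nearest_boundary = thickness_nearest_boundary(b),
               stop("unknown thickness method: ", cfg$thickness$method))
  write_volume(th$W, file.path(out_dir, "thickness.nii"))

  vm <- variance_map(th, radius_px = cfg$variance$radius_px)
  write_volume(vm, file.path(out_dir, "variance.nii"))

  summ <- summarize_thickness(th, cavity_volume_cm3 = b$diagnostics$cavity_volume_cm3)
  summ$pct_above_threshold <- fraction_above(th, cfg$stats$threshold_mm)
  summ$threshold_mm <- cfg$stats$threshold_mm
  utils::write.csv(summ, file.path(out_dir, "summary.csv"), row.names = FALSE)
  if (!is.null(region)) {
    rsumm <- summarize_thickness(th, mask = region)
    utils::write.csv(rsumm, file.path(out_dir, "summary_region.csv"), row.names = FALSE)
  }
  jsonlite::write_json(list(boundaries = b$diagnostics,
                            thickness_method = th$method),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(boundaries = b, chambers = chambers, thickness = th,
                 variance = vm, summary = summ, paths = out_dir))
}

#' Benchmark the thickness estimators on a phantom family
#'
#' Runs every requested method on each phantom and tabulates signed bias,
#' mean absolute error and maximum absolute error against the generator's
#' ground truth (transition voxels of ridged shells excluded).
#'
#' @param phantoms non-empty list of `awt_phantom` bundles (or a single
#'   bundle).
#' @param methods character vector among `"coupled_pde"`,
#'   `"laplace_streamline"`, `"nearest_boundary"`.
#' @param use_truth_boundaries use the generator's constructed boundary
#'   labels (default) rather than re-deriving them via the hull pipeline.
#' @return `data.frame` with one row per phantom x method.
#' @export
benchmark_methods <- function(phantoms,
                              methods = c("coupled_pde", "laplace_streamline",
                                          "nearest_boundary"),
                              use_truth_boundaries = TRUE) {
  if (inherits(phantoms, "awt_phantom")) phantoms <- list(phantoms)
  if (length(phantoms) == 0L) stop("empty phantom family")
  rows <- list()
  for (pi in seq_along(phantoms)) {
    ph <- phantoms[[pi]]
    b <- if (use_truth_boundaries && !is.null(ph$boundaries)) ph$boundaries
         else label_boundaries(ph$tissue)
    truth <- ph$truth_thickness$data
    keep <- is.finite(truth)
    if (!is.null(ph$transition)) keep <- keep & !vol_mask(ph$transition)
    for (m in methods) {
      th <- switch(m,
                   coupled_pde = thickness_coupled_pde(b),
                   laplace_streamline = thickness_laplace_streamline(b),
                   nearest_boundary = thickness_nearest_boundary(b),
                   stop("unknown method: ", m))
      W <- th$W$data
      ok <- keep & is.finite(W)
      err <- W[ok] - truth[ok]
      rows[[length(rows) + 1L]] <- data.frame(
        phantom = pi, kind = ph$spec$shape_kind, method = m,
        n_voxels = sum(ok), bias_mm = mean(err),
        mae_mm = mean(abs(err)), max_abs_mm = max(abs(err)))
    }
  }
  do.call(rbind, rows)
}
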