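#' Multi-planar convex-hull closure of a tissue mask
#'
#' For each of the three principal axes, the 2D convex hull of the tissue
#' voxels is computed in every slice perpendicular to that axis and filled
#' (exact integer half-plane tests on voxel centres); the returned hull is
#' the voxelwise intersection of the three filled stacks. It always contains
#' the tissue, contains the true 3D convex hull, and caps wall openings such
#' as vein ostia, which is the property the downstream cavity/exterior
#' separation needs.
#'
#' @param tissue binary `awt_volume`, non-empty.
#' @param method `"multiplanar"` (default) or `"hull3d"` for the exact 3D
#'   convex hull (support-function membership test; slower, intended for
#'   moderate volumes).
#' @return binary `awt_volume` with `hull >= tissue`.
#' @export
multiplanar_convex_hull <- function(tissue, method = c("multiplanar", "hull3d")) {
  method <- match.arg(method)
  stopifnot_binary(tissue, "tissue")
  m <- vol_int(tissue)
  if (sum(m) == 0L) stop("empty tissue mask")
  if (method == "multiplanar") {
    h <- cpp_multiplanar_hull(m, dim(m))
    return(as_volume(h, tissue$spacing, tissue$origin))
  }
  as_volume(hull3d_mask(m), tissue$spacing, tissue$origin)
}

# exact 3D convex hull occupancy: candidate vertices are the per-slice 2D
# hull vertices (any 3D-extreme point is extreme in its own slice); exact
# integer facet enumeration then classifies every voxel centre in the
# candidate bounding box. O(candidates^3) - meant for moderate volumes.
hull3d_mask <- function(m) {
  dims <- dim(m)
  cand <- cpp_slice_hull_vertices(m, dims)
  lo <- apply(cand, 2, min); hi <- apply(cand, 2, max)
  gi <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  storage.mode(gi) <- "integer"
  inh <- cpp_in_hull_exact(gi, cand)
  out <- array(0L, dims)
  out[gi[inh, , drop = FALSE] + 1L] <- 1L
  out[m == 1L] <- 1L
  out
}

# shared constructor for boundary labellings; used by label_boundaries and
# by the phantom generators (which know cavity/exterior by construction)
build_boundaries <- function(tissue, cavity, exterior, hull) {
  dims <- dim(tissue$data)
  tis <- vol_mask(tissue)
  cav <- vol_mask(cavity)
  ext <- vol_mask(exterior)
  adj <- function(mask) {
    a <- array(FALSE, dims)
    n <- dims
    a[-n[1], , ] <- a[-n[1], , ] | mask[-1, , ]
    a[-1, , ]    <- a[-1, , ]    | mask[-n[1], , ]
    a[, -n[2], ] <- a[, -n[2], ] | mask[, -1, ]
    a[, -1, ]    <- a[, -1, ]    | mask[, -n[2], ]
    a[, , -n[3]] <- a[, , -n[3]] | mask[, , -1]
    a[, , -1]    <- a[, , -1]    | mask[, , -n[3]]
    a
  }
  near_cav <- adj(cav) & tis
  near_ext <- adj(ext) & tis
  lab <- array(0L, dims)
  lab[tis] <- 1L
  lab[near_cav] <- 2L
  lab[near_ext] <- 3L
  lab[near_cav & near_ext] <- 4L
  sp <- tissue$spacing
  diag <- list(
    n_tissue = sum(tis),
    n_endocardial = sum(lab == 2L),
    n_epicardial = sum(lab == 3L),
    n_transmural_contact = sum(lab == 4L),
    cavity_volume_cm3 = sum(cav) * prod(sp) / 1000,
    tissue_volume_cm3 = sum(tis) * prod(sp) / 1000)
  structure(list(labels = as_volume(lab, sp, tissue$origin),
                 hull = hull, cavity = cavity, exterior = exterior,
                 tissue = tissue, diagnostics = diag),
            class = "awt_boundaries")
}

#' @export
print.awt_boundaries <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf(paste0("<awt_boundaries> %d tissue voxels: %d endocardial, ",
                     "%d epicardial, %d transmural-contact\n"),
              d$n_tissue, d$n_endocardial, d$n_epicardial, d$n_transmural_contact))
  cat(sprintf("  cavity %.2f cm^3, tissue %.2f cm^3\n",
              d$cavity_volume_cm3, d$tissue_volume_cm3))
  invisible(x)
}

#' Separate the endocardial and epicardial surfaces
#'
#' Classifies space around a hull-closed wall: the exterior is the connected
#' component of non-hull space touching the grid border (6-connectivity);
#' the cavity is every non-tissue voxel inside the hull. Tissue voxels
#' 6-adjacent to the cavity are endocardial, those adjacent to the exterior
#' epicardial; voxels adjacent to both are flagged `transmural_contact` (in
#' the label volume: 0 background, 1 interior, 2 endocardial, 3 epicardial,
#' 4 transmural contact).
#'
#' @param tissue binary `awt_volume`.
#' @param hull hull volume from [multiplanar_convex_hull()]; computed if
#'   missing. Must contain the tissue.
#' @return An `awt_boundaries` object (labels, hull, cavity, exterior,
#'   diagnostics).
#' @export
label_boundaries <- function(tissue, hull = NULL) {
  stopifnot_binary(tissue, "tissue")
  if (is.null(hull)) hull <- multiplanar_convex_hull(tissue)
  tis <- vol_mask(tissue)
  hm <- vol_mask(hull)
  if (any(tis & !hm)) stop("hull does not contain the tissue mask")
  dims <- dim(tis)
  nothull <- array(as.integer(!hm), dims)
  lab <- cpp_components(nothull, dims, 6L)
  border_labs <- unique(c(lab[1, , ], lab[dims[1], , ], lab[, 1, ],
                          lab[, dims[2], ], lab[, , 1], lab[, , dims[3]]))
  border_labs <- border_labs[border_labs > 0]
  ext <- array(lab %in% border_labs, dims)
  cav <- !tis & hm
  if (!any(cav))
    warning("no cavity found (solid object): all boundary is epicardial")
  build_boundaries(tissue,
                   as_volume(array(as.integer(cav), dims), tissue$spacing),
                   as_volume(array(as.integer(ext), dims), tissue$spacing),
                   hull)
}

# domain coding for the PDE kernels: 0 unclassified background (zero-flux),
# 1 tissue (solve), 2 cavity (endocardial face), 3 exterior (epicardial face)
codes_from_boundaries <- function(b) {
  dims <- dim(b$tissue$data)
  codes <- array(0L, dims)
  codes[vol_mask(b$cavity)] <- 2L
  codes[vol_mask(b$exterior)] <- 3L
  codes[vol_mask(b$tissue)] <- 1L
  codes
}

#' Write boundary labels and diagnostics
#'
#' @param boundaries an `awt_boundaries` object.
#' @param path output NIfTI path for the label volume; a `.json` sidecar
#'   with the diagnostics is written next to it.
#' @export
write_boundaries <- function(boundaries, path) {
  write_volume(boundaries$labels, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(boundaries$diagnostics, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
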