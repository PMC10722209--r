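#' Construct a voxel volume
#'
#' The universal carrier of the pipeline: a 3D array of scalars or integer
#' labels together with its per-axis voxel spacing in mm and a world origin.
#' Voxel centres sit at `index * spacing + spacing/2` (0-based indexing in
#' world terms; R arrays are addressed 1-based as usual).
#'
#' @param data 3D array (numeric, integer or logical).
#' @param spacing numeric length-3, mm per axis, strictly positive. A scalar
#'   is recycled to all three axes.
#' @param origin numeric length-3 world offset in mm (default zeros).
#' @return An object of class `awt_volume`.
#' @export
as_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive mm values")
  if (is.logical(data)) data <- array(as.integer(data), dim(data))
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin)),
            class = "awt_volume")
}

is_volume <- function(x) inherits(x, "awt_volume")

#' @export
dim.awt_volume <- function(x) dim(x$data)

#' @export
print.awt_volume <- function(x, ...) {
  cat(sprintf("<awt_volume> %s voxels, spacing %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  v <- x$data[is.finite(x$data)]
  if (length(v))
    cat(sprintf("  range [%g, %g], %d finite voxels\n", min(v), max(v), length(v)))
  invisible(x)
}

#' Volume of one voxel in mm^3
#' @param volume an `awt_volume`
#' @export
voxel_volume <- function(volume) prod(volume$spacing)

# logical tissue mask from a binary volume
vol_mask <- function(volume) {
  m <- volume$data != 0 & !is.na(volume$data)
  array(m, dim(volume$data))
}

# integer 0/1 array for C++ kernels
vol_int <- function(volume) array(as.integer(vol_mask(volume)), dim(volume$data))

stopifnot_binary <- function(volume, what = "volume") {
  vals <- unique(as.vector(volume$data))
  vals <- vals[!is.na(vals)]
  if (!all(vals %in% c(0, 1)))
    stop(sprintf("%s must be binary (0/1); found other values", what))
  invisible(TRUE)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-8))
}

#' Read a NIfTI-1 volume
#'
#' Accepts only axis-aligned affines (a diagonal rotation part, up to sign);
#' shear or rotation is rejected because all downstream geometry assumes an
#' axis-aligned grid.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `awt_volume` with spacing taken from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  xf <- RNifti::xform(img)
  rot <- abs(xf[1:3, 1:3])
  offd <- rot - diag(diag(rot))
  if (any(offd > 1e-6 * max(rot)))
    stop("non-axis-aligned affine (rotation/shear) is not supported: ", path)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(img)[1:3])
  as_volume(arr, spacing, origin = as.numeric(xf[1:3, 4]))
}

#' Write a volume as NIfTI-1
#'
#' @param volume an `awt_volume`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param datatype passed to [RNifti::writeNifti()]; `"auto"` keeps integer
#'   data integral so binary masks round-trip bit-exactly.
#' @export
write_volume <- function(volume, path, datatype = "auto") {
  stopifnot(is_volume(volume))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a binary mask to a new spacing
#'
#' Trilinear interpolation of the 0/1 mask followed by thresholding at 0.5
#' (ties count as tissue). The grid extent is preserved as closely as the
#' new spacing allows.
#'
#' @param volume binary `awt_volume`.
#' @param new_spacing target spacing, mm (scalar or length 3).
#' @return binary `awt_volume` at the new spacing.
#' @export
resample_mask <- function(volume, new_spacing) {
  stopifnot_binary(volume, "resample_mask input")
  if (length(new_spacing) == 1L) new_spacing <- rep(new_spacing, 3L)
  if (any(new_spacing <= 0)) stop("new_spacing must be positive")
  fac <- volume$spacing / new_spacing
  if (any(fac > 8)) stop("upsampling factor > 8 rejected (memory guard)")
  if (isTRUE(all.equal(as.numeric(new_spacing), volume$spacing))) return(volume)
  extent <- dim(volume$data) * volume$spacing
  newdim <- pmax(1L, as.integer(round(extent / new_spacing)))
  res <- cpp_resample(array(as.numeric(volume$data != 0), dim(volume$data)),
                      dim(volume$data), volume$spacing,
                      newdim, as.numeric(new_spacing))
  as_volume(array(as.integer(res >= 0.5), newdim), new_spacing, volume$origin)
}

#' Smooth a binary mask with a physical-size Gaussian
#'
#' Gaussian blur with per-axis sigma `sigma_mm / spacing` voxels (zero-padded
#' outside the grid), then thresholding at 0.5 (ties count as tissue). If the
#' smoothing changes the number of 6-connected components the change is
#' reported with a message.
#'
#' @param volume binary `awt_volume`.
#' @param sigma_mm Gaussian sigma in mm, `>= 0` (0 is the identity).
#' @return binary `awt_volume`.
#' @export
smooth_mask <- function(volume, sigma_mm) {
  stopifnot_binary(volume, "smooth_mask input")
  if (sigma_mm < 0) stop("sigma_mm must be >= 0")
  if (sigma_mm == 0) return(volume)
  sig_vox <- sigma_mm / volume$spacing
  sm <- cpp_gauss_blur(array(as.numeric(volume$data != 0), dim(volume$data)),
                       dim(volume$data), sig_vox)
  out <- as_volume(array(as.integer(sm >= 0.5), dim(volume$data)),
                   volume$spacing, volume$origin)
  n0 <- n_components(volume); n1 <- n_components(out)
  if (n0 != n1)
    message(sprintf("smooth_mask: component count changed %d -> %d", n0, n1))
  out
}

n_components <- function(volume, connectivity = 6) {
  lab <- cpp_components(vol_int(volume), dim(volume$data), as.integer(connectivity))
  max(lab)
}

#' Keep only the largest connected component of a mask
#'
#' @param volume binary `awt_volume`.
#' @param connectivity 6 (faces, the default) or 26 (faces+edges+corners).
#'   Size ties are broken in favour of the component whose first voxel has
#'   the lowest linear index.
#' @return binary `awt_volume` containing one component.
#' @export
largest_component <- function(volume, connectivity = 6) {
  stopifnot_binary(volume, "largest_component input")
  if (!any(vol_mask(volume))) stop("empty mask")
  lab <- cpp_components(vol_int(volume), dim(volume$data), as.integer(connectivity))
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)  # first maximum = lowest-index seed on ties
  as_volume(array(as.integer(lab == keep), dim(volume$data)),
            volume$spacing, volume$origin)
}
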