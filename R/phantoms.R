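#' @useDynLib atriawall, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats runif var sd median quantile pt pf
NULL

# voxel-centre coordinate arrays (mm) for a grid
centre_coords <- function(dims, spacing) {
  list(x = (seq_len(dims[1]) - 0.5) * spacing[1],
       y = (seq_len(dims[2]) - 0.5) * spacing[2],
       z = (seq_len(dims[3]) - 0.5) * spacing[3])
}

# squared distance of every voxel centre to a point (mm)
dist2_to_point <- function(dims, spacing, p) {
  cc <- centre_coords(dims, spacing)
  dx2 <- (cc$x - p[1])^2
  dy2 <- (cc$y - p[2])^2
  dz2 <- (cc$z - p[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

new_phantom <- function(tissue, truth, spec, chamber = NULL, region = NULL,
                        septum = NULL, transition = NULL, seeds = NULL,
                        boundaries = NULL) {
  structure(list(tissue = tissue, truth_thickness = truth, truth_chamber = chamber,
                 region_mask = region, septum = septum, transition = transition,
                 seeds = seeds, boundaries = boundaries, spec = spec),
            class = "awt_phantom")
}

#' @export
print.awt_phantom <- function(x, ...) {
  cat(sprintf("<awt_phantom> kind '%s', %d tissue voxels, spacing %s mm\n",
              x$spec$shape_kind, sum(vol_mask(x$tissue)),
              paste(signif(x$tissue$spacing, 4), collapse = "x")))
  invisible(x)
}

check_phantom_fit <- function(dims, spacing, centre, reach_mm) {
  lo <- centre - reach_mm
  hi <- centre + reach_mm
  margin <- 2 * spacing
  if (any(lo < margin) || any(hi > dims * spacing - margin))
    stop("phantom does not fit in the grid with a 2-voxel exterior margin")
}

apply_seed_jitter <- function(centre, spacing, seed) {
  if (is.null(seed)) return(centre)
  set.seed(as.integer(seed))
  centre + runif(3, -0.25, 0.25) * spacing
}

#' Flat-slab phantom of constant thickness
#'
#' A plate normal to the third axis, spanning the grid in x and y, with
#' ground-truth thickness equal to `thickness_mm` everywhere. Because the
#' slab touches the grid edge laterally, the bundle carries ready-made
#' boundary labels built by construction (the space below the plate is
#' declared cavity, a sealed-box convention used only by phantoms).
#'
#' @param thickness_mm plate thickness, mm; must span at least 2 voxels.
#' @param spacing voxel spacing, mm (scalar or length 3).
#' @param dims voxel counts per axis (scalar or length 3), `>= 8`.
#' @return An `awt_phantom` bundle.
#' @export
make_slab <- function(thickness_mm, spacing, dims) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(dims) == 1L) dims <- rep(as.integer(dims), 3L)
  dims <- as.integer(dims)
  if (any(dims < 8L)) stop("dims must be >= 8 per axis")
  if (thickness_mm < 2 * max(spacing))
    stop("slab thinner than 2 voxels is not representable on this grid")
  nvox <- round(thickness_mm / spacing[3])
  if (nvox < 2) stop("slab thinner than 2 voxels across the third axis")
  k0 <- floor((dims[3] - nvox) / 2)
  z0 <- k0 * spacing[3]
  cc <- centre_coords(dims, spacing)
  in_z <- cc$z >= z0 & cc$z < z0 + thickness_mm
  tis <- array(0L, dims)
  tis[, , which(in_z)] <- 1L
  tissue <- as_volume(tis, spacing)
  truth <- array(NA_real_, dims)
  truth[tis == 1L] <- thickness_mm
  cav <- array(0L, dims); cav[, , which(cc$z < z0)] <- 1L
  ext <- array(0L, dims); ext[, , which(cc$z >= z0 + thickness_mm)] <- 1L
  hull <- array(1L, dims); hull[ext == 1L] <- 0L
  b <- build_boundaries(tissue,
                        as_volume(cav, spacing), as_volume(ext, spacing),
                        as_volume(hull, spacing))
  spec <- list(shape_kind = "slab", thickness_mm = thickness_mm,
               spacing = spacing, dims = dims)
  new_phantom(tissue, as_volume(truth, spacing), spec, boundaries = b)
}

#' Spherical-shell phantom
#'
#' Tissue is every voxel whose centre lies at distance `r_in <= d <= r_out`
#' from the grid centre; ground truth is the constant `r_out - r_in`.
#'
#' @param r_in,r_out inner and outer radii, mm, `r_out > r_in`.
#' @param spacing voxel spacing, mm.
#' @param dims voxel counts (scalar or length 3); `NULL` auto-fits the grid.
#' @param seed optional integer: jitters the centre by up to a quarter voxel
#'   (deterministic given the seed) to de-align the shell from the grid.
#' @return An `awt_phantom` bundle.
#' @export
make_spherical_shell <- function(r_in, r_out, spacing, dims = NULL, seed = NULL) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (!(r_out > r_in) || r_in <= 2 * max(spacing))
    stop("need r_out > r_in > 2*max(spacing)")
  if (r_out - r_in < 2 * max(spacing))
    stop("shell wall thinner than 2 voxels")
  if (is.null(dims)) dims <- ceiling((2 * r_out + 6 * spacing) / spacing)
  if (length(dims) == 1L) dims <- rep(as.integer(dims), 3L)
  dims <- as.integer(dims)
  centre <- dims * spacing / 2
  centre <- apply_seed_jitter(centre, spacing, seed)
  check_phantom_fit(dims, spacing, centre, r_out)
  d2 <- dist2_to_point(dims, spacing, centre)
  tis <- array(as.integer(d2 >= r_in^2 & d2 <= r_out^2), dims)
  tissue <- as_volume(tis, spacing)
  truth <- array(NA_real_, dims)
  truth[tis == 1L] <- r_out - r_in
  cav <- as_volume(array(as.integer(d2 < r_in^2), dims), spacing)
  ext <- as_volume(array(as.integer(d2 > r_out^2), dims), spacing)
  hull <- as_volume(array(as.integer(d2 <= r_out^2), dims), spacing)
  b <- build_boundaries(tissue, cav, ext, hull)
  spec <- list(shape_kind = "spherical_shell", r_in = r_in, r_out = r_out,
               spacing = spacing, dims = dims, centre = centre, seed = seed)
  new_phantom(tissue, as_volume(truth, spacing), spec, boundaries = b)
}

# dense quasi-uniform sample of an ellipsoid surface (Fibonacci sphere
# mapped through the semi-axes); the ground-truth oracle's point cloud
ellipsoid_surface_points <- function(semi, n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(semi[1] * sin(phi) * cos(theta),
        semi[2] * sin(phi) * sin(theta),
        semi[3] * cos(phi))
}

#' Ellipsoidal-shell phantom with a sampled-surface thickness oracle
#'
#' Tissue lies between two concentric axis-aligned ellipsoids. The
#' ground-truth thickness at each tissue voxel is computed by an independent
#' geometric oracle: the shortest distance to the inner surface plus the
#' shortest distance to the outer surface, each obtained by dense surface
#' point sampling (`n_surface_points` quasi-uniform points per surface).
#'
#' @param semi_in,semi_out inner/outer semi-axes, mm (length 3); each outer
#'   semi-axis must exceed the corresponding inner one.
#' @param spacing voxel spacing, mm.
#' @param dims voxel counts; `NULL` auto-fits.
#' @param n_surface_points oracle sampling density per surface.
#' @return An `awt_phantom` bundle.
#' @export
make_ellipsoidal_shell <- function(semi_in, semi_out, spacing, dims = NULL,
                                   n_surface_points = 20000L) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(semi_in) != 3L || length(semi_out) != 3L || any(semi_out <= semi_in))
    stop("each outer semi-axis must exceed the corresponding inner one")
  if (is.null(dims)) dims <- ceiling((2 * semi_out + 6 * spacing) / spacing)
  if (length(dims) == 1L) dims <- rep(as.integer(dims), 3L)
  dims <- as.integer(dims)
  centre <- dims * spacing / 2
  check_phantom_fit(dims, spacing, centre, semi_out)
  cc <- centre_coords(dims, spacing)
  qi <- outer(outer((cc$x - centre[1])^2 / semi_in[1]^2,
                    (cc$y - centre[2])^2 / semi_in[2]^2, `+`),
              (cc$z - centre[3])^2 / semi_in[3]^2, `+`)
  qo <- outer(outer((cc$x - centre[1])^2 / semi_out[1]^2,
                    (cc$y - centre[2])^2 / semi_out[2]^2, `+`),
              (cc$z - centre[3])^2 / semi_out[3]^2, `+`)
  tis <- array(as.integer(qi >= 1 & qo <= 1), dims)
  tissue <- as_volume(tis, spacing)
  idx <- which(tis == 1L, arr.ind = TRUE)
  pts <- cbind((idx[, 1] - 0.5) * spacing[1] - centre[1],
               (idx[, 2] - 0.5) * spacing[2] - centre[2],
               (idx[, 3] - 0.5) * spacing[3] - centre[3])
  d_in <- cpp_min_dist(pts, ellipsoid_surface_points(semi_in, n_surface_points))
  d_out <- cpp_min_dist(pts, ellipsoid_surface_points(semi_out, n_surface_points))
  truth <- array(NA_real_, dims)
  truth[tis == 1L] <- d_in + d_out
  cav <- as_volume(array(as.integer(qi < 1), dims), spacing)
  ext <- as_volume(array(as.integer(qo > 1), dims), spacing)
  hull <- as_volume(array(as.integer(qo <= 1), dims), spacing)
  b <- build_boundaries(tissue, cav, ext, hull)
  spec <- list(shape_kind = "ellipsoidal_shell", semi_in = semi_in,
               semi_out = semi_out, spacing = spacing, dims = dims,
               centre = centre, n_surface_points = n_surface_points)
  new_phantom(tissue, as_volume(truth, spacing), spec, boundaries = b)
}

#' Ridged spherical shell (crista-terminalis-like thick band)
#'
#' A spherical shell whose wall is locally thickened inward along a
#' great-circle (equatorial) band covering `ridge_fraction` of the surface,
#' producing a bimodal thickness distribution with modes at the base
#' thickness and base + `ridge_extra_mm`. The ridge carries its full extra
#' depth on the band plateau and merges into the base wall over a smooth
#' cosine flank (a real crista terminalis blends into the wall rather than
#' ending in a cliff; a sharp-edged trench would expose side walls that no
#' transmural measure reads as ridge thickness). Flank voxels are flagged
#' as transition voxels: their ground truth follows the taper and they are
#' excluded from mode-location assertions.
#'
#' The defaults are sized like an adult atrium (inner radius 30 mm, 4 mm
#' base wall): at that scale a 15\%-of-surface equatorial band is about
#' 9 mm wide, comparable to a real crista terminalis, so its 8 mm total
#' thickness is transmurally resolvable. On much smaller shells the same
#' surface fraction degenerates into a deep narrow fin whose trajectory
#' thickness is width- rather than depth-limited.
#'
#' @param r_in,r_out base shell radii, mm.
#' @param spacing voxel spacing, mm.
#' @param ridge_extra_mm extra inward thickness inside the band, mm, `> 0`
#'   (0 returns a plain shell).
#' @param ridge_fraction fraction of the sphere surface covered by the
#'   full-depth band plateau (an equatorial band `|z|/r <= f` covers
#'   fraction `f`).
#' @param taper_fraction additional angular width (in the same `|z|/r`
#'   units) of the cosine flank on each side of the plateau.
#' @param dims voxel counts; `NULL` auto-fits.
#' @param seed optional centre jitter seed (see [make_spherical_shell()]).
#' @return An `awt_phantom` bundle.
#' @export
make_ridged_shell <- function(r_in = 30, r_out = 34, spacing = 0.5,
                              ridge_extra_mm = 4,
                              ridge_fraction = 0.15, taper_fraction = 0.20,
                              dims = NULL, seed = NULL) {
  if (ridge_extra_mm < 0) stop("ridge_extra_mm must be >= 0")
  if (ridge_extra_mm == 0)
    return(make_spherical_shell(r_in, r_out, spacing, dims, seed))
  if (r_in - ridge_extra_mm <= 2 * max(if (length(spacing) == 1) rep(spacing, 3) else spacing))
    stop("ridge thicker than the inner radius allows")
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (is.null(dims)) dims <- ceiling((2 * r_out + 6 * spacing) / spacing)
  if (length(dims) == 1L) dims <- rep(as.integer(dims), 3L)
  dims <- as.integer(dims)
  centre <- dims * spacing / 2
  centre <- apply_seed_jitter(centre, spacing, seed)
  check_phantom_fit(dims, spacing, centre, r_out)
  cc <- centre_coords(dims, spacing)
  d2 <- dist2_to_point(dims, spacing, centre)
  d <- sqrt(d2)
  zrel <- array(rep(cc$z - centre[3], each = dims[1] * dims[2]), dims)
  sinlat <- abs(zrel) / pmax(d, 1e-9)        # |cos(polar angle)|
  taper <- array(0, dims)
  taper[sinlat <= ridge_fraction] <- 1
  fl <- sinlat > ridge_fraction & sinlat <= ridge_fraction + taper_fraction
  taper[fl] <- 0.5 * (1 + cos(pi * (sinlat[fl] - ridge_fraction) / taper_fraction))
  r_floor <- r_in - ridge_extra_mm * taper
  tis <- array(as.integer(d >= r_floor & d <= r_out), dims)
  tissue <- as_volume(tis, spacing)
  # ground truth: radial wall depth corrected by the local slope of the
  # tapered inner surface (perpendicular width of a locally planar wedge);
  # on the plateau and base wall the correction is identically 1
  dtaper <- array(0, dims)
  dtaper[fl] <- 0.5 * pi / taper_fraction *
    abs(sin(pi * (sinlat[fl] - ridge_fraction) / taper_fraction))
  coslat <- sqrt(pmax(0, 1 - sinlat^2))
  slope <- ridge_extra_mm * dtaper * coslat / pmax(d, 1e-9)
  truth <- array(NA_real_, dims)
  truth[tis == 1L] <- ((r_out - r_in) + ridge_extra_mm * taper[tis == 1L]) *
    cos(atan(slope[tis == 1L]))
  ang_halfvox <- max(spacing) / r_in
  trans <- array(as.integer(tis == 1L & sinlat > ridge_fraction - ang_halfvox &
                              sinlat <= ridge_fraction + taper_fraction + ang_halfvox), dims)
  cav <- as_volume(array(as.integer(d < r_floor), dims), spacing)
  ext <- as_volume(array(as.integer(d > r_out), dims), spacing)
  hull <- as_volume(array(as.integer(d <= r_out), dims), spacing)
  b <- build_boundaries(tissue, cav, ext, hull)
  spec <- list(shape_kind = "ridged_shell", r_in = r_in, r_out = r_out,
               ridge_extra_mm = ridge_extra_mm, ridge_fraction = ridge_fraction,
               spacing = spacing, dims = dims, centre = centre, seed = seed)
  new_phantom(tissue, as_volume(truth, spacing), spec,
              transition = as_volume(trans, spacing), boundaries = b)
}

#' Two fused spherical shells sharing a septum
#'
#' Two identical shells whose walls overlap along a planar septum band,
#' emulating the fused right and left atrial chambers. Every tissue voxel is
#' labelled by its side of the perpendicular bisector plane of the two
#' centres (chamber 1 on the low-x side, chamber 2 on the high-x side), and
#' seed patches on the two outward-facing poles are emitted for the
#' Laplace chamber delineation.
#'
#' @param r_in,r_out shell radii, mm.
#' @param centre_sep distance between the two shell centres, mm; the shells
#'   must overlap (`centre_sep < 2*r_out`).
#' @param spacing voxel spacing, mm.
#' @param dims voxel counts; `NULL` auto-fits.
#' @param seed_patch_mm radius of the polar seed patches, mm.
#' @return An `awt_phantom` bundle with `truth_chamber`, `septum` and
#'   `seeds` (`$chamber1`, `$chamber2` voxel-index matrices) populated.
#' @export
make_two_chamber <- function(r_in, r_out, centre_sep, spacing, dims = NULL,
                             seed_patch_mm = 3) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (centre_sep >= 2 * r_out) stop("shells disjoint: no shared septum")
  if (centre_sep <= 2 * r_in)
    stop("inner cavities overlap: septum would not separate the chambers")
  if (is.null(dims)) {
    ext <- c(centre_sep + 2 * r_out, 2 * r_out, 2 * r_out) + 6 * spacing
    dims <- ceiling(ext / spacing)
  }
  if (length(dims) == 1L) dims <- rep(as.integer(dims), 3L)
  dims <- as.integer(dims)
  mid <- dims * spacing / 2
  cA <- mid - c(centre_sep / 2, 0, 0)
  cB <- mid + c(centre_sep / 2, 0, 0)
  check_phantom_fit(dims, spacing, cA, r_out)
  check_phantom_fit(dims, spacing, cB, r_out)
  dA2 <- dist2_to_point(dims, spacing, cA)
  dB2 <- dist2_to_point(dims, spacing, cB)
  shellA <- dA2 >= r_in^2 & dA2 <= r_out^2
  shellB <- dB2 >= r_in^2 & dB2 <= r_out^2
  tis <- array(as.integer(shellA | shellB), dims)
  tissue <- as_volume(tis, spacing)
  cc <- centre_coords(dims, spacing)
  xarr <- array(rep(cc$x, times = dims[2] * dims[3]), dims)
  cham <- array(0L, dims)
  cham[tis == 1L & xarr < mid[1]] <- 1L
  cham[tis == 1L & xarr >= mid[1]] <- 2L
  septum <- array(as.integer(tis == 1L &
                               ((dA2 <= r_out^2 & dB2 <= r_out^2) |
                                  abs(xarr - mid[1]) <= max(spacing))), dims)
  pole <- function(p) {
    d2 <- dist2_to_point(dims, spacing, p)
    which(tis == 1L & d2 <= seed_patch_mm^2, arr.ind = TRUE)
  }
  r_mid <- (r_in + r_out) / 2
  seeds <- list(chamber1 = pole(cA - c(r_mid, 0, 0)),
                chamber2 = pole(cB + c(r_mid, 0, 0)))
  if (nrow(seeds$chamber1) == 0L || nrow(seeds$chamber2) == 0L)
    stop("empty seed patch; increase seed_patch_mm")
  truth <- array(NA_real_, dims)
  truth[tis == 1L] <- r_out - r_in   # nominal; not exact inside the septum lens
  spec <- list(shape_kind = "two_chamber", r_in = r_in, r_out = r_out,
               centre_sep = centre_sep, spacing = spacing, dims = dims,
               centres = rbind(cA, cB))
  new_phantom(tissue, as_volume(truth, spacing), spec,
              chamber = as_volume(cham, spacing),
              septum = as_volume(septum, spacing), seeds = seeds)
}

#' Spherical region-of-interest mask on a phantom
#'
#' All tissue voxels within `radius_mm` (Euclidean, mm, between voxel
#' centres) of a chosen tissue voxel - the stand-in for an optically mapped
#' driver-region patch.
#'
#' @param bundle an `awt_phantom`.
#' @param centre_voxel 1-based voxel index (length 3) of a tissue voxel.
#' @param radius_mm patch radius, mm (`0` selects only the centre voxel).
#' @return binary `awt_volume`.
#' @export
make_region_mask <- function(bundle, centre_voxel, radius_mm) {
  tis <- vol_mask(bundle$tissue)
  dims <- dim(tis)
  cv <- as.integer(centre_voxel)
  if (!tis[cv[1], cv[2], cv[3]]) stop("centre voxel is not tissue")
  sp <- bundle$tissue$spacing
  p <- (cv - 0.5) * sp
  d2 <- dist2_to_point(dims, sp, p)
  m <- array(as.integer(tis & d2 <= radius_mm^2), dims)
  if (sum(m) == 0L) stop("empty region mask")
  as_volume(m, sp)
}
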