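#' Harmonic potential across the wall
#'
#' Solves the Laplace equation over the wall voxels with Dirichlet value 0
#' on the endocardial surface and 1 on the epicardial surface. The Dirichlet
#' surfaces are imposed at the tissue/cavity and tissue/exterior voxel
#' *faces* by reflection ghosts (`u_ghost = -u` on the endocardial side,
#' `2 - u` on the epicardial side), so on a slab of K voxels the discrete
#' solution is exactly `u(k) = (k + 1/2)/K`; wall voxels whose neighbours
#' leave the tissue without a boundary label get zero-flux conditions.
#' 7-point finite differences with anisotropic `1/spacing^2` weights,
#' red-black Gauss-Seidel.
#'
#' @param boundaries an `awt_boundaries` object (both surface types must be
#'   present in every connected wall component).
#' @param tol maximum-update convergence tolerance.
#' @param max_iter maximum sweeps; default `10 * N^(2/3)`.
#' @param omega over-relaxation factor (1 = plain Gauss-Seidel).
#' @param method `"gauss_seidel"` or `"jacobi"` (for sweep-order checks).
#' @return An `awt_potential` object: `u` (volume, NA off wall), `residual`,
#'   `iterations`, and the domain `codes` used by downstream solvers.
#' @export
solve_wall_laplace <- function(boundaries, tol = 1e-6, max_iter = NULL,
                               omega = 1.7, method = c("gauss_seidel", "jacobi")) {
  method <- match.arg(method)
  codes <- codes_from_boundaries(boundaries)
  dims <- dim(codes)
  tis <- codes == 1L
  if (!any(tis)) stop("empty wall")
  lab <- boundaries$labels$data
  comp <- cpp_components(array(as.integer(tis), dims), dims, 6L)
  for (cid in seq_len(max(comp))) {
    inb <- comp == cid
    has_endo <- any(lab[inb] %in% c(2L, 4L))
    has_epi <- any(lab[inb] %in% c(3L, 4L))
    if (!has_endo || !has_epi)
      stop(sprintf("wall component %d has only one boundary type (%s)", cid,
                   if (has_endo) "endocardial" else if (has_epi) "epicardial" else "none"))
  }
  n <- sum(tis)
  if (is.null(max_iter)) max_iter <- ceiling(10 * n^(2 / 3))
  if (method == "jacobi") omega <- 1  # over-relaxed Jacobi diverges
  sol <- cpp_laplace(codes, dims, boundaries$tissue$spacing, tol,
                     as.integer(max_iter), omega, method == "jacobi")
  if (!is.finite(sol$residual) || sol$residual > tol)
    stop(sprintf("wall Laplace did not converge: residual %.3g after %d sweeps",
                 sol$residual, sol$iterations))
  structure(list(u = as_volume(sol$u, boundaries$tissue$spacing),
                 residual = sol$residual, iterations = sol$iterations,
                 codes = codes, spacing = boundaries$tissue$spacing),
            class = "awt_potential")
}

#' Unit tangent field of the wall potential
#'
#' Central differences of the harmonic potential scaled by the physical
#' spacing (one-sided at unlabelled domain edges, reflection-ghost values at
#' the Dirichlet faces), normalised to unit length. Voxels where the
#' gradient norm falls below `eps_grad` are flagged degenerate; they are
#' later filled by neighbour averaging in the transport solve.
#'
#' @param potential an `awt_potential` from [solve_wall_laplace()].
#' @param eps_grad degenerate-gradient threshold (1/mm scale).
#' @return An `awt_tangent` object with `Tx`, `Ty`, `Tz`, `grad_norm`,
#'   `degenerate` arrays and the domain codes.
#' @export
tangent_field <- function(potential, eps_grad = 1e-8) {
  tf <- cpp_tangent(potential$u$data, potential$codes, dim(potential$codes),
                    potential$spacing, eps_grad)
  structure(c(tf, list(codes = potential$codes, spacing = potential$spacing)),
            class = "awt_tangent")
}

#' Trajectory-length transport equations
#'
#' Solves the two first-order transport equations of the coupled-PDE
#' thickness method with first-order upwind differencing and Gauss-Seidel
#' sweeps in alternating orderings: `grad(L0) . T = 1` with `L0 = 0` on the
#' endocardial face and `-grad(L1) . T = 1` with `L1 = 0` on the epicardial
#' face (a half-voxel face correction keeps the pair unbiased: the exit
#' faces contribute `-spacing/2` to the upwind stencil). Degenerate-tangent
#' voxels receive values by 6-neighbour averaging and stay flagged.
#'
#' @param tangent an `awt_tangent` from [tangent_field()].
#' @param tol maximum-update convergence tolerance (mm).
#' @param max_iter maximum sweeps.
#' @return An `awt_trajectories` object with `L0`, `L1` volumes (mm),
#'   per-equation iteration/residual reports and flagged-voxel counts.
#' @export
solve_trajectory_lengths <- function(tangent, tol = 1e-4, max_iter = 2000L) {
  dims <- dim(tangent$codes)
  r0 <- cpp_transport(tangent$Tx, tangent$Ty, tangent$Tz, tangent$codes, dims,
                      tangent$spacing, -1L, 2L, tol, as.integer(max_iter),
                      tangent$degenerate)
  r1 <- cpp_transport(tangent$Tx, tangent$Ty, tangent$Tz, tangent$codes, dims,
                      tangent$spacing, 1L, 3L, tol, as.integer(max_iter),
                      tangent$degenerate)
  if (r0$residual > tol || r1$residual > tol)
    stop(sprintf("transport solve did not converge: residuals %.3g / %.3g",
                 r0$residual, r1$residual))
  structure(list(L0 = as_volume(r0$L, tangent$spacing),
                 L1 = as_volume(r1$L, tangent$spacing),
                 flagged = r0$flagged | r1$flagged,
                 n_flagged = max(r0$n_flagged, r1$n_flagged),
                 report = list(L0 = r0[c("iterations", "residual")],
                               L1 = r1[c("iterations", "residual")])),
            class = "awt_trajectories")
}

new_thickness <- function(W, method, spacing, extra = list()) {
  structure(c(list(W = as_volume(W, spacing), method = method), extra),
            class = "awt_thickness")
}

#' @export
print.awt_thickness <- function(x, ...) {
  w <- x$W$data[is.finite(x$W$data)]
  cat(sprintf("<awt_thickness> method '%s': %d wall voxels, mean %.2f mm, sd %.2f mm\n",
              x$method, length(w), mean(w), sd(w)))
  invisible(x)
}

#' Coupled-PDE wall thickness (W = L0 + L1)
#'
#' The primary thickness estimator: solve the harmonic potential across the
#' wall, follow its normalised gradient, and solve the two trajectory-length
#' transport equations; thickness at a wall voxel is the total trajectory
#' arc length `W = L0 + L1` in mm.
#'
#' @param boundaries an `awt_boundaries` object.
#' @param tol,max_iter solver controls, applied to the Laplace stage
#'   (`tol`) and transport stage (`10 * tol`).
#' @param eps_grad degenerate-gradient threshold for the tangent field.
#' @return An `awt_thickness` object (`W` plus the intermediate `potential`,
#'   `tangent`, `trajectories` and a `report`).
#' @export
thickness_coupled_pde <- function(boundaries, tol = 1e-6, max_iter = NULL,
                                  eps_grad = 1e-8) {
  pot <- solve_wall_laplace(boundaries, tol = tol, max_iter = max_iter)
  tang <- tangent_field(pot, eps_grad = eps_grad)
  traj <- solve_trajectory_lengths(tang, tol = max(10 * tol, 1e-8))
  W <- traj$L0$data + traj$L1$data
  new_thickness(W, "coupled_pde", boundaries$tissue$spacing,
                list(potential = pot, tangent = tang, trajectories = traj,
                     report = list(laplace = pot[c("iterations", "residual")],
                                   transport = traj$report,
                                   n_flagged = traj$n_flagged)))
}

#' Laplace-streamline wall thickness (explicit trajectory integration)
#'
#' For each wall voxel, a streamline of the unit tangent field is integrated
#' forward to the epicardium and backward to the endocardium with fixed-step
#' midpoint (RK2) stepping and trilinear interpolation; thickness is the
#' total arc length. Slower than the coupled-PDE solver, and doubles as its
#' brute-force oracle.
#'
#' @param boundaries an `awt_boundaries` object.
#' @param step_mm integration step; default half the smallest spacing.
#' @param tol Laplace tolerance for the underlying potential.
#' @param max_steps step budget per direction; default ten grid diagonals.
#' @return An `awt_thickness` object with an `unresolved` flag volume.
#' @export
thickness_laplace_streamline <- function(boundaries, step_mm = NULL, tol = 1e-6,
                                         max_steps = NULL) {
  sp <- boundaries$tissue$spacing
  if (is.null(step_mm)) step_mm <- min(sp) / 2
  dims <- dim(boundaries$tissue$data)
  if (is.null(max_steps))
    max_steps <- ceiling(10 * sqrt(sum((dims * sp)^2)) / step_mm)
  pot <- solve_wall_laplace(boundaries, tol = tol)
  tang <- tangent_field(pot)
  tis <- vol_int(boundaries$tissue)
  extf <- cpp_extend_field(tang$Tx, tang$Ty, tang$Tz, tis, dims, 3L)
  res <- cpp_streamline(extf$Tx, extf$Ty, extf$Tz, tis, dims, sp,
                        step_mm, as.integer(max_steps))
  new_thickness(res$W, "laplace_streamline", sp,
                list(L0 = as_volume(res$L0, sp), L1 = as_volume(res$L1, sp),
                     unresolved = res$unresolved, step_mm = step_mm))
}

#' Nearest-boundary wall thickness (distance-transform baseline)
#'
#' Thickness as the Euclidean distance to the nearest endocardial voxel
#' centre plus the distance to the nearest epicardial voxel centre, via
#' exact (Felzenszwalb) distance transforms. A fast sanity baseline that is
#' a lower bound on trajectory-based thickness and underestimates at curved
#' or oblique walls.
#'
#' @param boundaries an `awt_boundaries` object.
#' @return An `awt_thickness` object.
#' @export
thickness_nearest_boundary <- function(boundaries) {
  lab <- boundaries$labels$data
  dims <- dim(lab)
  sp <- boundaries$tissue$spacing
  endo <- array(as.integer(lab == 2L | lab == 4L), dims)
  epi <- array(as.integer(lab == 3L | lab == 4L), dims)
  if (sum(endo) == 0L || sum(epi) == 0L)
    stop("both endocardial and epicardial voxels are required")
  d0 <- cpp_edt(endo, dims, sp)
  d1 <- cpp_edt(epi, dims, sp)
  W <- d0 + d1
  W[lab == 0L] <- NA_real_
  new_thickness(W, "nearest_boundary", sp)
}

#' Local thickness-variance map
#'
#' Population variance of the thickness field over the wall voxels whose
#' index-space Euclidean distance from each voxel is at most `radius_px`
#' (the voxel itself included; neighbourhoods are clipped to the wall mask).
#' The radius is interpreted in pixels even under anisotropic spacing;
#' `radius_mm` switches to a physical radius instead.
#'
#' @param thickness an `awt_thickness` object (or a thickness `awt_volume`
#'   paired with `mask`).
#' @param radius_px neighbourhood radius in voxels (default 3).
#' @param mask optional binary `awt_volume` wall mask; defaults to the
#'   finite support of the thickness field.
#' @param radius_mm optional physical radius in mm; overrides `radius_px`
#'   using the smallest spacing (off by default).
#' @return `awt_volume` of per-voxel variance (mm^2), NA off the wall.
#' @export
variance_map <- function(thickness, radius_px = 3, mask = NULL, radius_mm = NULL) {
  Wvol <- if (inherits(thickness, "awt_thickness")) thickness$W else thickness
  W <- Wvol$data
  dims <- dim(W)
  m <- if (is.null(mask)) array(as.integer(is.finite(W)), dims) else vol_int(mask)
  if (!is.null(radius_mm)) radius_px <- radius_mm / min(Wvol$spacing)
  Wz <- W
  Wz[!is.finite(Wz)] <- 0
  v <- cpp_local_variance(Wz, m, dims, radius_px)
  as_volume(v, Wvol$spacing)
}
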