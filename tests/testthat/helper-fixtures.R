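# Shared phantom fixtures, built once per test run. All generation is
# deterministic, so caching only saves time.
.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, maker) {
  if (is.null(.fx_cache[[name]])) assign(name, maker(), envir = .fx_cache)
  .fx_cache[[name]]
}

fx_slab <- function() fx("slab", function() make_slab(4.0, 0.5, 32))
fx_slab_pde <- function() fx("slab_pde", function() thickness_coupled_pde(fx_slab()$boundaries))

fx_shell <- function() fx("shell", function() make_spherical_shell(10, 14, 0.5, 64))
fx_shell_pde <- function() fx("shell_pde", function() thickness_coupled_pde(fx_shell()$boundaries))
fx_shell_stream <- function() fx("shell_stream", function() thickness_laplace_streamline(fx_shell()$boundaries))

fx_ellipsoid <- function() fx("ellipsoid", function()
  make_ellipsoidal_shell(c(8, 10, 12), c(12, 14, 16), 0.5))
fx_ellipsoid_pde <- function() fx("ellipsoid_pde", function() thickness_coupled_pde(fx_ellipsoid()$boundaries))
fx_ellipsoid_stream <- function() fx("ellipsoid_stream", function() thickness_laplace_streamline(fx_ellipsoid()$boundaries))

fx_ridged <- function() fx("ridged", function() make_ridged_shell())
fx_ridged_pde <- function() fx("ridged_pde", function() thickness_coupled_pde(fx_ridged()$boundaries))

fx_two_chamber <- function() fx("two_chamber", function() make_two_chamber(10, 14, 22, 0.5))
fx_two_chamber_lab <- function() fx("two_chamber_lab", function() {
  ph <- fx_two_chamber()
  delineate_chambers(ph$tissue, ph$seeds$chamber1, ph$seeds$chamber2)
})

# radius of every wall voxel of a centred phantom, in mm
wall_radii <- function(ph, mask = is.finite(ph$truth_thickness$data)) {
  idx <- which(mask, arr.ind = TRUE)
  sp <- ph$tissue$spacing
  p <- t(t(idx) - 0.5) * rep(sp, each = nrow(idx))
  sqrt(colSums((t(p) - ph$spec$centre)^2))
}

# density-based locations of the two dominant modes of a sample
two_modes <- function(x, bw = 0.2) {
  d <- stats::density(x, bw = bw)
  pk <- which(diff(sign(diff(d$y))) == -2) + 1
  pk <- pk[order(d$y[pk], decreasing = TRUE)][1:2]
  sort(d$x[pk])
}
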