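test_that("wall potential is exactly linear through a slab", {
  ph <- fx_slab()
  pot <- solve_wall_laplace(ph$boundaries)
  u <- pot$u$data
  ks <- which(apply(is.finite(u), 3, any))
  K <- length(ks)
  for (i in seq_along(ks)) {
    uk <- u[, , ks[i]]
    expect_lt(max(abs(uk[is.finite(uk)] - (i - 0.5) / K)), 1e-4)
  }
  expect_lte(pot$residual, 1e-6)
})

test_that("wall potential matches the radial closed form on a shell", {
  ph <- fx_shell()
  pot <- solve_wall_laplace(ph$boundaries)
  fin <- is.finite(pot$u$data)
  r <- wall_radii(ph, fin)
  u <- pot$u$data[fin]
  ucf <- function(r) (1 / 10 - 1 / r) / (1 / 10 - 1 / 14)
  # radial profile agrees with the closed form to 0.02
  bins <- cut(r, seq(10, 14, 0.25))
  prof_err <- tapply(u, bins, mean) - ucf(tapply(r, bins, mean))
  expect_lt(max(abs(prof_err)), 0.02)
  # pointwise error is bounded by the half-voxel surface quantisation
  expect_lt(max(abs(u - ucf(r))), 0.08)
  # face-interface boundary conditions: u within half a voxel-step of its
  # Dirichlet value on the surface voxels
  lab <- ph$boundaries$labels$data[fin]
  expect_lt(max(u[lab == 2L]), 0.15)
  expect_gt(min(u[lab == 3L]), 0.85)
  expect_gte(min(u), 0); expect_lte(max(u), 1)
})

test_that("wall potential agrees with a dense linear solve of the same stencil", {
  # tiny slab wall: 6x6x4 tissue with cavity below and exterior above
  ph <- make_slab(2.0, 0.5, 8)
  tol <- 1e-10
  pot <- solve_wall_laplace(ph$boundaries, tol = tol)
  codes <- atriawall:::codes_from_boundaries(ph$boundaries)
  dims <- dim(codes)
  solve_idx <- which(codes == 1L)
  n <- length(solve_idx)
  pos <- match(seq_len(prod(dims)), solve_idx)
  A <- matrix(0, n, n); rhs <- numeric(n)
  sp <- ph$tissue$spacing
  w <- 1 / sp^2
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  ai <- arrayInd(solve_idx, dims)
  for (q in seq_len(n)) {
    for (t in 1:6) {
      nb <- ai[q, ] + offs[t, ]
      if (any(nb < 1) || any(nb > dims)) next
      wt <- w[which(offs[t, ] != 0)]
      cn <- codes[nb[1], nb[2], nb[3]]
      if (cn == 1L) {
        j <- pos[nb[1] + dims[1] * (nb[2] - 1) + dims[1] * dims[2] * (nb[3] - 1)]
        A[q, j] <- A[q, j] + wt
        A[q, q] <- A[q, q] - wt
      } else if (cn == 2L) {
        A[q, q] <- A[q, q] - 2 * wt          # face Dirichlet 0
      } else if (cn == 3L) {
        A[q, q] <- A[q, q] - 2 * wt          # face Dirichlet 1
        rhs[q] <- rhs[q] - 2 * wt
      }
    }
  }
  u_dense <- solve(A, rhs)
  expect_lt(max(abs(pot$u$data[solve_idx] - u_dense)), 10 * tol)
})

test_that("tangent field is axial on a slab and radial on a shell", {
  ph <- fx_slab()
  pot <- solve_wall_laplace(ph$boundaries)
  tg <- tangent_field(pot)
  wall <- tg$codes == 1L
  expect_true(all(abs(tg$Tz[wall]) >= 1 - 1e-9))
  expect_equal(sum(tg$degenerate), 0)
  phs <- fx_shell()
  tgs <- tangent_field(solve_wall_laplace(phs$boundaries))
  expect_equal(sum(tgs$degenerate), 0)
  walls <- tgs$codes == 1L
  idx <- which(walls, arr.ind = TRUE)
  p <- t(t(idx) - 0.5) * 0.5
  rv <- p - matrix(phs$spec$centre, nrow(p), 3, byrow = TRUE)
  rn <- rv / sqrt(rowSums(rv^2))
  dp <- rn[, 1] * tgs$Tx[walls] + rn[, 2] * tgs$Ty[walls] + rn[, 3] * tgs$Tz[walls]
  interior <- phs$boundaries$labels$data[walls] == 1L
  expect_gte(mean(dp[interior] >= 0.99), 0.99)
  expect_gte(min(dp[interior]), 0.98)
})

test_that("trajectory lengths solve the transport pair on slab and shell", {
  ph <- fx_slab()
  tg <- tangent_field(solve_wall_laplace(ph$boundaries))
  tr <- solve_trajectory_lengths(tg)
  wall <- tg$codes == 1L
  W <- tr$L0$data[wall] + tr$L1$data[wall]
  expect_lt(max(abs(W - 4.0)), 0.5)            # within one voxel everywhere
  # L0 grows linearly with z
  idx <- which(wall, arr.ind = TRUE)
  ks <- sort(unique(idx[, 3]))
  L0k <- vapply(ks, function(k) mean(tr$L0$data[, , k], na.rm = TRUE), 0)
  expect_equal(L0k, (seq_along(ks) - 0.5) * 0.5, tolerance = 1e-6)
  phs <- fx_shell()
  tgs <- tangent_field(solve_wall_laplace(phs$boundaries))
  trs <- solve_trajectory_lengths(tgs)
  fin <- is.finite(trs$L0$data)
  r <- wall_radii(phs, fin)
  expect_lt(max(abs(trs$L0$data[fin] - (r - 10))), 0.75)   # 1.5 voxel sizes
  expect_lt(max(abs(trs$L1$data[fin] - (14 - r))), 0.75)
  expect_gte(min(trs$L0$data[fin]), 0)
  expect_gte(min(trs$L1$data[fin]), 0)
})

test_that("coupled-PDE thickness recovers analytic truths", {
  th <- fx_slab_pde()
  W <- th$W$data[is.finite(th$W$data)]
  expect_lt(abs(mean(W) - 4.0) / 4.0, 0.02)
  expect_lte(sqrt(mean((W - mean(W))^2)), 0.1)
  ths <- fx_shell_pde()
  Ws <- ths$W$data[is.finite(ths$W$data)]
  expect_lt(abs(mean(Ws) - 4.0) / 4.0, 0.05)
})

test_that("streamline thickness matches analytic truths and the coupled PDE", {
  ph <- fx_slab()
  th <- thickness_laplace_streamline(ph$boundaries)
  W <- th$W$data[is.finite(th$W$data)]
  expect_lt(max(abs(W - 4.0)), th$step_mm / 2 + 1e-6)
  expect_equal(sum(th$unresolved), 0)
  ths <- fx_shell_stream()
  Ws <- ths$W$data[is.finite(ths$W$data)]
  interior <- fx_shell()$boundaries$labels$data[is.finite(ths$W$data)] == 1L
  # unbiased in the mean; pointwise spread is set by the half-voxel jitter
  # of the voxelised exit surfaces at either end of each streamline
  expect_lt(abs(mean(Ws[interior]) - 4.0) / 4.0, 0.03)
  expect_lt(max(abs(Ws[interior] - 4.0)), 0.75)
  # cross-method oracle on the ellipsoid
  d <- abs(fx_ellipsoid_pde()$W$data - fx_ellipsoid_stream()$W$data)
  d <- d[is.finite(d)]
  expect_lte(median(d), 0.5)
  expect_lte(quantile(d, 0.95), 1.0)
})

test_that("nearest-boundary thickness is an exact lower-bound baseline", {
  ph <- fx_slab()
  tnb <- thickness_nearest_boundary(ph$boundaries)
  tpde <- fx_slab_pde()
  fin <- is.finite(tnb$W$data) & is.finite(tpde$W$data)
  expect_lte(max(abs(tnb$W$data[fin] - tpde$W$data[fin])), 0.5 + 1e-9)
  phs <- fx_shell()
  nb <- thickness_nearest_boundary(phs$boundaries)$W$data
  pde <- fx_shell_pde()$W$data
  fin <- is.finite(nb) & is.finite(pde)
  # lower bound up to the voxel-centre (nearest) vs surface-face (PDE)
  # endpoint conventions, which differ by at most a voxel
  expect_true(all(nb[fin] <= pde[fin] + 0.5))
  expect_lt(mean(nb[fin]), mean(pde[fin]))
  # exact match with a brute-force all-pairs scan on a small toy wall
  toy <- make_spherical_shell(2, 4, 0.5, 20)
  b <- toy$boundaries
  W <- thickness_nearest_boundary(b)$W$data
  lab <- b$labels$data
  wall <- which(lab > 0L, arr.ind = TRUE)
  endo <- which(lab == 2L, arr.ind = TRUE)
  epi <- which(lab == 3L, arr.ind = TRUE)
  dmin <- function(P, Q) {
    apply(P, 1, function(p)
      min(sqrt(colSums((t(Q) * 0.5 - p * 0.5)^2))))
  }
  Wb <- dmin(wall, endo) + dmin(wall, epi)
  expect_equal(W[lab > 0L], Wb, tolerance = 1e-12)
})

test_that("variance map matches a brute-force neighbourhood scan exactly", {
  set.seed(5)
  dims <- c(12L, 12L, 12L)
  mask <- array(as.integer(runif(prod(dims)) > 0.35), dims)
  W <- array(rnorm(prod(dims), 4, 1), dims)
  W[mask == 0L] <- NA_real_
  v <- variance_map(as_volume(W, 0.5), radius_px = 3)
  offs <- expand.grid(-3:3, -3:3, -3:3)
  offs <- offs[rowSums(offs^2) <= 9, ]
  brute <- array(NA_real_, dims)
  for (q in which(mask == 1L)) {
    a <- arrayInd(q, dims)
    nb <- sweep(as.matrix(offs), 2, as.integer(a), `+`)
    keep <- nb[, 1] >= 1 & nb[, 2] >= 1 & nb[, 3] >= 1 &
      nb[, 1] <= 12 & nb[, 2] <= 12 & nb[, 3] <= 12
    vals <- W[nb[keep, , drop = FALSE]]
    vals <- vals[is.finite(vals)]
    brute[q] <- mean((vals - mean(vals))^2)
  }
  expect_equal(v$data[mask == 1L], brute[mask == 1L], tolerance = 1e-12)
  # constant fields have zero variance; an outlier is felt only within 3 px
  Wc <- array(2.5, dims)
  vc <- variance_map(as_volume(Wc, 0.5), radius_px = 3,
                     mask = as_volume(array(1L, dims), 0.5))
  expect_true(all(vc$data == 0))
  Wo <- array(1.0, dims); Wo[6, 6, 6] <- 9
  vo <- variance_map(as_volume(Wo, 0.5), radius_px = 3,
                     mask = as_volume(array(1L, dims), 0.5))
  idx <- which(array(TRUE, dims), arr.ind = TRUE)
  d2 <- rowSums(sweep(idx, 2, c(6, 6, 6))^2)
  expect_true(all(vo$data[d2 > 9] == 0))
  expect_true(all(vo$data[d2 <= 9] > 0))
})

test_that("thickness is invariant under axis permutations and scales linearly", {
  ph <- make_spherical_shell(5, 7, 0.5, 36)
  th <- thickness_coupled_pde(ph$boundaries)
  for (perm in list(c(2, 1, 3), c(3, 2, 1))) {
    rot <- as_volume(aperm(ph$tissue$data, perm), ph$tissue$spacing[perm])
    br <- label_boundaries(rot)
    thr <- thickness_coupled_pde(br)
    dW <- abs(aperm(th$W$data, perm) - thr$W$data)
    expect_lt(max(dW[is.finite(dW)]), 0.5)
  }
  # doubling all lengths and the spacing doubles W voxel-for-voxel
  a <- make_slab(4, 0.5, 16)
  b <- make_slab(8, 1.0, 16)
  Wa <- thickness_coupled_pde(a$boundaries)$W$data
  Wb <- thickness_coupled_pde(b$boundaries)$W$data
  fin <- is.finite(Wa)
  expect_equal(Wb[fin], 2 * Wa[fin], tolerance = 1e-9)
})

test_that("total trajectory length is conserved along streamlines", {
  ths <- fx_shell_stream()
  ph <- fx_shell()
  # step one voxel along the local tangent: W must be nearly unchanged
  tg <- tangent_field(solve_wall_laplace(ph$boundaries))
  wall <- which(ph$boundaries$labels$data == 1L, arr.ind = TRUE)
  set.seed(9)
  pick <- wall[sample(nrow(wall), 200), ]
  for (q in seq_len(nrow(pick))) {
    i <- pick[q, 1]; j <- pick[q, 2]; k <- pick[q, 3]
    stp <- round(c(tg$Tx[i, j, k], tg$Ty[i, j, k], tg$Tz[i, j, k]))
    nb <- c(i, j, k) + stp
    w0 <- ths$W$data[i, j, k]; w1 <- ths$W$data[nb[1], nb[2], nb[3]]
    if (is.finite(w0) && is.finite(w1))
      expect_lt(abs(w1 - w0), 1.0)             # two voxel sizes
  }
})

test_that("wall components lacking one surface type are rejected", {
  # a floating plate inside a sealed box has no epicardial contact
  ph <- fx_slab()
  b <- ph$boundaries
  codes_ok <- atriawall:::codes_from_boundaries(b)
  expect_true(all(c(2L, 3L) %in% unique(as.vector(codes_ok))))
  b_bad <- b
  b_bad$exterior$data[] <- 0L
  b_bad$labels$data[b_bad$labels$data == 3L] <- 1L
  expect_error(solve_wall_laplace(b_bad), "only one boundary type")
})
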