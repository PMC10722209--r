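test_that("hull of a convex solid is the solid itself", {
  a <- array(0L, c(16, 16, 16))
  a[4:12, 4:12, 4:12] <- 1L
  v <- as_volume(a, 1)
  expect_identical(multiplanar_convex_hull(v)$data, a)
  expect_error(multiplanar_convex_hull(as_volume(array(0L, c(8, 8, 8)), 1)),
               "empty")
})

test_that("hull closes a spherical shell over its cavity", {
  ph <- fx_shell()
  h <- multiplanar_convex_hull(ph$tissue)
  tis <- ph$tissue$data == 1L
  expect_true(all(h$data[tis] == 1L))
  # the cavity ball is inside the hull
  inner <- is.finite(ph$truth_thickness$data)  # wall
  cav <- ph$boundaries$cavity$data == 1L
  expect_true(all(h$data[cav] == 1L))
  # idempotency = every slice is already convex
  expect_identical(multiplanar_convex_hull(as_volume(h$data, ph$tissue$spacing))$data,
                   h$data)
})

test_that("multiplanar hull is sandwiched between tissue and the true 3D hull", {
  # L-shaped solid: the multiplanar hull is strictly tighter than the 3D hull
  dims <- c(20L, 20L, 20L)
  a <- array(0L, dims)
  a[3:16, 3:8, 3:16] <- 1L
  a[3:8, 3:16, 3:16] <- 1L
  v <- as_volume(a, 1)
  mp <- multiplanar_convex_hull(v)$data
  h3 <- multiplanar_convex_hull(v, method = "hull3d")$data
  expect_true(all(mp[a == 1L] == 1L))
  expect_true(all(h3[mp == 1L] == 1L))      # mp subset of 3D hull
  expect_lt(sum(mp), sum(h3))               # strictly smaller on the L
  # independent oracle: scipy Delaunay membership on the same point set
  pts_f <- tempfile(fileext = ".csv"); q_f <- tempfile(fileext = ".csv")
  out_f <- tempfile(fileext = ".txt"); py_f <- tempfile(fileext = ".py")
  write.table(which(a == 1L, arr.ind = TRUE) - 1L, pts_f,
              row.names = FALSE, col.names = FALSE, sep = ",")
  write.table(which(array(TRUE, dims), arr.ind = TRUE) - 1L, q_f,
              row.names = FALSE, col.names = FALSE, sep = ",")
  writeLines(c(
    "import sys, numpy as np",
    "from scipy.spatial import Delaunay",
    "p = np.loadtxt(sys.argv[1], delimiter=',')",
    "q = np.loadtxt(sys.argv[2], delimiter=',')",
    "d = Delaunay(p)",
    "np.savetxt(sys.argv[3], (d.find_simplex(q) >= 0).astype(int), fmt='%d')"),
    py_f)
  status <- system2("python", c(py_f, pts_f, q_f, out_f))
  expect_equal(status, 0)
  oracle <- array(as.integer(readLines(out_f)), dims)
  expect_true(all(oracle[mp == 1L] == 1L))  # mp subset of oracle 3D hull
  expect_identical(h3, oracle)              # exact hull3d equals the oracle
})

test_that("boundary labelling separates endo- and epicardium on a shell", {
  ph <- fx_shell()
  b <- label_boundaries(ph$tissue)
  lab <- b$labels$data
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L, 3L))
  expect_equal(b$diagnostics$n_transmural_contact, 0)
  # boundary voxels have a non-tissue 6-neighbour of the right class
  r <- wall_radii(ph, lab > 0L)
  expect_true(all(r[lab[lab > 0L] == 2L] < 11))   # endo near the inner surface
  expect_true(all(r[lab[lab > 0L] == 3L] > 13))   # epi near the outer surface
  expect_equal(b$diagnostics$cavity_volume_cm3,
               sum(ph$boundaries$cavity$data) * voxel_volume(ph$tissue) / 1000)
})

test_that("a solid object yields an all-epicardial boundary with a warning", {
  a <- array(0L, c(12, 12, 12))
  a[4:9, 4:9, 4:9] <- 1L
  v <- as_volume(a, 1)
  expect_warning(b <- label_boundaries(v), "solid")
  lab <- b$labels$data
  expect_equal(sum(lab == 2L), 0)
  expect_gt(sum(lab == 3L), 0)
})

test_that("the hull caps a vein-ostium-like hole and keeps the cavity enclosed", {
  ph <- make_spherical_shell(7, 10, 0.5, 48)
  holed <- ph$tissue
  # cut a ~3-voxel channel through the wall along +z at the pole
  ctr <- round(dim(holed$data) / 2)
  holed$data[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1),
             ctr[3]:dim(holed$data)[3]] <- 0L
  b0 <- label_boundaries(ph$tissue)
  b1 <- label_boundaries(holed)
  # cavity still enclosed: its voxels are not exterior
  expect_gt(sum(b1$cavity$data), 0)
  expect_equal(sum(b1$cavity$data & b1$exterior$data), 0)
  n0 <- sum(b0$labels$data == 2L)
  n1 <- sum(b1$labels$data == 2L)
  expect_lt(abs(n1 - n0) / n0, 0.05)
})

test_that("boundary labelling is invariant under 90-degree grid rotations", {
  ph <- make_spherical_shell(5, 7, 0.5, 36)
  b <- label_boundaries(ph$tissue)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    rot <- as_volume(aperm(ph$tissue$data, perm), ph$tissue$spacing[perm])
    br <- label_boundaries(rot)
    expect_identical(br$labels$data, aperm(b$labels$data, perm))
  }
})
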