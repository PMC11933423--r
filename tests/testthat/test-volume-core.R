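test_that("coordinate tables parse, validate and count correctly", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study\tx\ty\tz", "s1\t1\t2\t3", "s1\t-4\t5.5\t6",
               "s1\t0\t0\t0"), p)
  tab <- read_coordinate_table(p)
  expect_equal(n_rows(tab), 3)
  expect_equal(n_studies(tab), 1)
  expect_equal(tab$x, c(1, -4, 0))
  expect_equal(unique(tab$modality), "unknown")

  # missing coordinate column is a hard error
  p2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study\tx\ty", "s1\t1\t2"), p2)
  expect_error(read_coordinate_table(p2), "missing column")

  # non-numeric coordinate reports the study
  p3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("study\tx\ty\tz", "s9\tfoo\t2\t3"), p3)
  expect_error(read_coordinate_table(p3), "s9")

  # empty file
  p4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("study\tx\ty\tz", p4)
  expect_error(read_coordinate_table(p4), "no rows")
})

test_that("the literature-emulation preset round-trips with 21 studies and 131 foci", {
  tab <- synth_ige_coordinates(small_model(), seed = 7L)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_coordinate_table(tab, p)
  back <- read_coordinate_table(p)
  expect_equal(n_studies(back), 21)
  expect_equal(n_rows(back), 131)
  expect_equal(back$x, tab$x)
})

test_that("mm/voxel conversions invert exactly on lattice points", {
  g <- box_grid(c(5L, 5L, 5L))
  expect_equal(as.integer(mm_to_voxel(g, c(0, 0, 0))$ijk), c(0L, 0L, 0L))

  # 2 mm isotropic with origin at voxel (10,10,10)
  g2 <- volume_grid(c(24L, 24L, 24L),
                    rbind(cbind(diag(c(2, 2, 2)), c(-20, -20, -20)),
                          c(0, 0, 0, 1)))
  conv <- mm_to_voxel(g2, c(2, 0, -2))
  expect_equal(as.integer(conv$ijk), c(11L, 10L, 9L))
  expect_true(conv$in_bounds)

  # exhaustive round trip on a random (rotated + translated) affine
  set.seed(1)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  aff <- rbind(cbind(rot %*% diag(c(2, 2.5, 3)), rnorm(3, sd = 10)),
               c(0, 0, 0, 1))
  g3 <- volume_grid(c(5L, 5L, 5L), aff)
  ijk <- as.matrix(expand.grid(0:4, 0:4, 0:4))
  conv3 <- mm_to_voxel(g3, voxel_to_mm(g3, ijk))
  expect_equal(unname(conv3$ijk), unname(ijk))
  expect_true(all(conv3$in_bounds))
})

test_that("sphere rasterization matches brute force and is symmetric", {
  g <- box_grid(c(9L, 9L, 9L))
  ctr <- as.numeric(voxel_to_mm(g, c(4L, 4L, 4L)))

  # diameter 0 keeps exactly the center voxel
  m0 <- rasterize_sphere(g, ctr, 0)
  expect_equal(sum(m0), 1)
  expect_true(m0[5, 5, 5])

  # 6 mm diameter on a 1 mm grid: brute force over all voxel centers
  m6 <- rasterize_sphere(g, ctr, 6)
  d <- sqrt(colSums((t(g$coords_mm) - ctr)^2))
  expect_equal(sum(m6), sum(d <= 3 + 1e-9))

  # mirror symmetry through the center
  idx <- which(m6, arr.ind = TRUE)
  mirrored <- 10L - idx  # reflect 1-based indices through voxel (5,5,5)
  expect_true(all(m6[mirrored]))

  # center far outside the mask errors with the coordinate
  expect_error(rasterize_sphere(g, c(500, 0, 0), 6), "500")
})

test_that("sphere volume approaches (pi/6) d^3 as voxels shrink", {
  for (cfg in list(list(vox = 1, tol = 0.15), list(vox = 0.5, tol = 0.05))) {
    n <- ceiling(8 / cfg$vox) + 1L
    g <- box_grid(rep(n, 3), voxel_mm = cfg$vox)
    ctr <- as.numeric(voxel_to_mm(g, rep((n - 1L) %/% 2L, 3)))
    m <- rasterize_sphere(g, ctr, 6)
    vol <- sum(m) * cfg$vox^3
    expect_lt(abs(vol - pi / 6 * 6^3) / (pi / 6 * 6^3), cfg$tol)
  }
})

test_that("study-seed union is a set union and monotone", {
  g <- box_grid(c(11L, 11L, 11L))
  s1 <- rasterize_sphere(g, c(2, 2, 2), 3)
  s2 <- rasterize_sphere(g, c(8, 8, 8), 3)
  s3 <- rasterize_sphere(g, c(3, 2, 2), 3)  # overlaps s1

  expect_equal(combine_study_seed(list(s1)), s1)
  expect_equal(sum(combine_study_seed(list(s1, s2))), sum(s1) + sum(s2))
  u <- combine_study_seed(list(s1, s3))
  expect_equal(sum(u), sum(s1 | s3))
  # adding a sphere never removes voxels
  u2 <- combine_study_seed(list(s1, s3, s2))
  expect_true(all(u2[u]))
  expect_error(combine_study_seed(list(s1, array(TRUE, c(2, 2, 2)))),
               "mismatch")
})

test_that("NIfTI round trip preserves values and affine", {
  g <- small_grid()
  set.seed(4)
  m <- stat_map(g, rnorm(n_mask_voxels(g)), kind = "weighted")
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(m, p)
  back <- read_volume(p, grid = g)
  expect_lt(max(abs(back$values - m$values)), 1e-12)
  expect_equal(back$grid$affine, g$affine)

  # wrong dimensionality
  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, dim = c(3, 3, 3, 2))), p4)
  expect_error(read_volume(p4), "3-D")

  # shape mismatch against expected grid
  g2 <- default_grid(c(10L, 10L, 10L), 3)
  expect_error(read_volume(p, grid = g2), "shape")
})

test_that("stat_map enforces kind-specific invariants", {
  g <- box_grid(c(3L, 3L, 3L))
  expect_error(stat_map(g, array(0.5, dim = c(3, 3, 3)), kind = "ternary"),
               "ternary")
  expect_error(stat_map(g, array(1.5, dim = c(3, 3, 3)), kind = "overlap"),
               "overlap")
  m <- stat_map(small_grid(), rep(1, n_mask_voxels(small_grid())), "overlap")
  expect_true(all(m$values[!small_grid()$mask] == 0))
})

test_that("ROI sets validate masks and survive a manifest round trip", {
  g <- small_grid()
  ctr <- colMeans(g$coords_mm[g$mask_idx, ])
  rs <- roi_set(g, list(a = rasterize_sphere(g, ctr, 12),
                        b = rasterize_sphere(g, ctr + c(12, 0, 0), 12)),
                groups = c("g1", "g2"))
  d <- withr::local_tempdir()
  man <- write_roi_set(rs, d)
  back <- read_roi_set(file.path(d, "manifest.tsv"), g)
  expect_equal(back$masks$a, rs$masks$a)
  expect_equal(back$groups, c("g1", "g2"))
  expect_error(roi_set(g, list(bad = array(FALSE, g$shape))), "empty")
})
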