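test_that("seed time series is the unweighted voxel mean", {
  g <- box_grid(c(4L, 4L, 4L))
  set.seed(3)
  X <- matrix(rnorm(64 * 10), nrow = 64)
  conn <- fake_connectome(g, list(X))
  one <- array(FALSE, g$shape); one[2, 2, 2] <- TRUE
  row1 <- match(which(one), g$mask_idx)
  expect_equal(seed_timeseries(conn, 1, one), X[row1, ])

  two <- one; two[3, 2, 2] <- TRUE
  rows <- match(which(two), g$mask_idx)
  expect_equal(seed_timeseries(conn, 1, two),
               colMeans(X[rows, ]))

  big <- array(FALSE, g$shape); big[1:3, 1:2, 4] <- TRUE
  rows <- match(which(big), g$mask_idx)
  brute <- vapply(1:10, function(t) mean(X[rows, t]), numeric(1))
  expect_equal(seed_timeseries(conn, 1, big), brute)

  expect_error(seed_timeseries(conn, 1, array(FALSE, g$shape)), "seed")
})

test_that("seed-to-voxel maps reproduce Pearson correlation exactly", {
  g <- box_grid(c(4L, 4L, 4L))
  set.seed(5)
  X <- matrix(rnorm(64 * 30), nrow = 64)
  seed_vox <- array(FALSE, g$shape); seed_vox[1, 1, 1] <- TRUE
  conn <- fake_connectome(g, list(X))

  rmap <- seed_to_voxel_map(conn, 1, seed_vox, fisher_z = FALSE)
  vals <- mask_values(rmap)
  # r = 1 at the seed voxel itself
  expect_equal(vals[match(which(seed_vox), g$mask_idx)], 1)
  # oracle: covariance formula voxel by voxel
  s <- X[match(which(seed_vox), g$mask_idx), ]
  brute <- apply(X, 1, function(v)
    sum((v - mean(v)) * (s - mean(s))) / sqrt(sum((v - mean(v))^2) *
                                                sum((s - mean(s))^2)))
  expect_lt(max(abs(vals - brute)), 1e-12)

  # a voxel holding the negated seed series correlates at -1
  X2 <- X; X2[10, ] <- -X2[1, ]
  seed1 <- array(FALSE, g$shape); seed1[g$mask_idx[1]] <- TRUE
  r2 <- mask_values(seed_to_voxel_map(fake_connectome(g, list(X2)), 1,
                                      seed1, fisher_z = FALSE))
  expect_equal(r2[10], -1)

  # zero-variance seed errors; zero-variance voxel is flagged as 0
  X3 <- X; X3[1, ] <- 0
  expect_error(seed_to_voxel_map(fake_connectome(g, list(X3)), 1, seed1),
               "variance")
  X4 <- X; X4[12, ] <- 5
  z4 <- seed_to_voxel_map(fake_connectome(g, list(X4)), 1, seed1)
  expect_equal(mask_values(z4)[12], 0)
  expect_equal(z4$n_zero_var, 1)
})

test_that("group t-maps match one-sample t statistics", {
  g <- box_grid(c(3L, 3L, 3L))
  # hand arithmetic: z = (1,2,3) -> t = 2/(1/sqrt(3))
  Z <- matrix(0, nrow = 3, ncol = 27)
  Z[, 5] <- c(1, 2, 3)
  tm <- group_t_map(Z, grid = g)
  expect_equal(mask_values(tm)[5], 2 / (1 / sqrt(3)))
  expect_equal(mask_values(tm)[1], 0)  # all-zero voxel (zero mean, zero sd)

  # oracle on random data: t.test per voxel
  set.seed(8)
  Zr <- matrix(rnorm(6 * 27), nrow = 6)
  tr <- mask_values(group_t_map(Zr, grid = g))
  brute <- apply(Zr, 2, function(v) unname(t.test(v)$statistic))
  expect_lt(max(abs(tr - brute)), 1e-10)

  # degenerate voxel: constant nonzero -> signed infinity, flagged
  Zd <- Zr; Zd[, 3] <- 2
  td <- group_t_map(Zd, grid = g)
  expect_identical(mask_values(td)[3], Inf)
  expect_equal(td$n_degenerate, 1)
})

test_that("ternarization applies strict signed thresholds", {
  g <- box_grid(c(3L, 3L, 3L))
  v <- rep(0, 27); v[1] <- 5.2; v[2] <- -5.2; v[3] <- 5.1; v[4] <- -5.1
  tm <- stat_map(g, array(v, c(3, 3, 3)), kind = "t")
  sn <- ternarize(tm, 5.1)
  tv <- mask_values(sn$ternary)
  expect_equal(tv[1:4], c(1, -1, 0, 0))

  # nonzero count is non-increasing in the threshold
  set.seed(2)
  tm2 <- stat_map(g, array(rnorm(27, sd = 6), c(3, 3, 3)), kind = "t")
  counts <- vapply(c(4.7, 5.1, 5.6, 7, 9), function(th)
    sum(mask_values(ternarize(tm2, th)$ternary) != 0), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("overlap maps are the signed study proportion", {
  g <- box_grid(c(3L, 3L, 3L))
  mk <- function(v) ternarize(stat_map(g, array(v * 10, c(3, 3, 3)),
                                       kind = "t"), 5.1)
  # 21 studies all +1 at every voxel
  ov1 <- overlap_map(replicate(21, mk(rep(1, 27)), simplify = FALSE))
  expect_true(all(mask_values(ov1) == 1))
  # 18 of 20 at +1, 2 at 0
  nets <- c(replicate(18, mk(rep(1, 27)), simplify = FALSE),
            replicate(2, mk(rep(0, 27)), simplify = FALSE))
  expect_true(all(mask_values(overlap_map(nets)) == 0.9))

  # oracle on random ternary stacks + integrality invariant
  set.seed(9)
  stack <- replicate(7, sample(c(-1, 0, 1), 27, replace = TRUE))
  nets <- lapply(seq_len(7), function(i) mk(stack[, i]))
  ov <- overlap_map(nets)
  expect_equal(mask_values(ov), rowMeans(stack))
  expect_equal(mask_values(ov) * 7, round(mask_values(ov) * 7))
  expect_true(all(abs(mask_values(ov)) <= 1))
})

test_that("study networks localize their own seed and respect modes", {
  m <- small_model(); conn <- small_connectome(); g <- small_grid()
  ctr <- g$coords_mm[g$mask_idx[which.max(m$components[[1]][g$mask_idx])], ]
  tab <- as_coordinate_table(data.frame(study_id = "solo",
                                        x = ctr[1], y = ctr[2], z = ctr[3]))
  nets <- run_study_networks(tab, conn, seed_diameter_mm = 6)
  expect_length(nets, 1)
  # t-map peak inside or adjacent to the seed
  seed <- rasterize_sphere(g, ctr, 6)
  pk <- peak_voxel(nets[[1]]$tmap)
  grown <- rasterize_sphere(g, ctr, 6 + 2 * max(abs(diag(g$affine)[1:3])))
  expect_true(grown[1L + pk$ijk[1] + g$shape[1] *
                      (pk$ijk[2] + g$shape[2] * pk$ijk[3])])

  # per-coordinate mode yields one network per focus
  tab3 <- as_coordinate_table(data.frame(
    study_id = "s", x = ctr[1] + c(0, 8, -8), y = ctr[2], z = ctr[3]))
  expect_length(run_study_networks(tab3, conn, per_coordinate = TRUE), 3)

  # shuffling coordinate rows leaves the overlap map unchanged
  tab5 <- small_coords()
  set.seed(1)
  shuf <- tab5[sample.int(nrow(tab5)), ]
  class(shuf) <- c("coordinate_table", "data.frame")
  ov1 <- overlap_map(run_study_networks(tab5, conn))
  ov2 <- overlap_map(run_study_networks(shuf, conn))
  expect_equal(ov1$values, ov2$values)
})

test_that("overlap maps are stable across the published threshold set", {
  nets47 <- lapply(small_networks(), function(n) ternarize(n$tmap, 4.7))
  nets51 <- small_networks()
  nets56 <- lapply(small_networks(), function(n) ternarize(n$tmap, 5.6))
  o47 <- overlap_map(nets47); o51 <- overlap_map(nets51)
  o56 <- overlap_map(nets56)
  expect_gt(spatial_correlation(o47, o51), 0.8)
  expect_gt(spatial_correlation(o51, o56), 0.8)
  expect_gt(spatial_correlation(o47, o56), 0.8)
})

test_that("the FWE-equivalent t helper matches the Bonferroni quantile", {
  expect_equal(fwe_t_threshold(40, 100000, 0.01),
               qt(1 - 0.01 / 200000, 39))
  expect_gt(fwe_t_threshold(652, 200000, 0.01), 5)
})
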