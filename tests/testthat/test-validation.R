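test_that("network overlap percent follows the mask-mean formula with sign", {
  g <- box_grid(c(4L, 4L, 4L))
  roi <- array(FALSE, g$shape); roi[1:2, 1:2, 1:2] <- TRUE
  mk <- function(x) stat_map(g, array(x, g$shape), kind = "weighted")
  expect_equal(network_overlap_percent(mk(1), roi), 100)
  expect_equal(network_overlap_percent(mk(0.5), roi), 50)
  expect_equal(network_overlap_percent(mk(-1), roi), -100)
  # linear in the map
  set.seed(1)
  m <- mk(rnorm(64))
  expect_equal(network_overlap_percent(stat_map(g, 3.7 * m$values,
                                                "weighted"), roi),
               3.7 * network_overlap_percent(m, roi))
  expect_error(network_overlap_percent(mk(1), array(FALSE, g$shape)),
               "empty")
})

test_that("parcel-null p-values behave analytically and under the null", {
  g <- small_grid()
  parc <- generate_parcellation(g, 68, seed = 3L)
  # network that is maximal exactly on one parcel
  v <- array(0, g$shape); v[parc$masks[[10]]] <- 1
  net <- stat_map(g, v, kind = "weighted")
  res <- parcel_null_test(net, parc$masks[[10]], parc, n_samples = 10000,
                          seed = 4L)
  # the drawn parcel ties/exceeds the observed only when it IS parcel 10
  p_true <- 1 / 68
  mc_se <- sqrt(p_true * (1 - p_true) / 10000)
  expect_lt(abs(res$p_value - p_true), 3 * mc_se + 2e-4)

  # constant network: every parcel scores the same; p must not be small
  cn <- stat_map(g, array(1, g$shape), kind = "weighted")
  ps <- vapply(1:5, function(i)
    parcel_null_test(cn, parc$masks[[i]], parc, n_samples = 500,
                     seed = i)$p_value, numeric(1))
  expect_true(all(ps >= 0.3))
  expect_error(parcel_null_test(net, parc$masks[[1]], parc, n_samples = 0),
               "n_samples")
})

test_that("group overlap t-test is a two-sided Welch test", {
  r0 <- group_overlap_ttest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0); expect_equal(r0$p, 1)

  a <- c(10, 11, 12); b <- c(0, 1, 2, 5)
  r <- group_overlap_ttest(a, b)
  # brute-force Welch formula
  se <- sqrt(var(a) / 3 + var(b) / 4)
  t_brute <- (mean(a) - mean(b)) / se
  df_brute <- se^4 / ((var(a) / 3)^2 / 2 + (var(b) / 4)^2 / 3)
  expect_lt(abs(r$t - t_brute), 1e-10)
  expect_lt(abs(r$df - df_brute), 1e-10)
  # swap antisymmetry
  r2 <- group_overlap_ttest(b, a)
  expect_equal(r2$t, -r$t)
  expect_equal(r2$p, r$p)
  # degenerate equal-mean constant groups
  expect_equal(group_overlap_ttest(c(2, 2), c(2, 2))$p, 1)
})

test_that("spatial correlation is scale-invariant Pearson r over the mask", {
  g <- small_grid()
  set.seed(5)
  a <- stat_map(g, rnorm(n_mask_voxels(g)), kind = "weighted")
  b <- stat_map(g, rnorm(n_mask_voxels(g)), kind = "weighted")
  expect_equal(spatial_correlation(a, a), 1)
  neg <- stat_map(g, -a$values, "weighted")
  expect_equal(spatial_correlation(a, neg), -1)
  r <- spatial_correlation(a, b)
  scaled <- stat_map(g, 2.5 * a$values + array(7, g$shape), "weighted")
  expect_lt(abs(spatial_correlation(scaled, b) - r), 1e-12)
  const <- stat_map(g, array(1, g$shape), "weighted")
  expect_error(spatial_correlation(a, const), "constant")
})

test_that("ROI-to-ROI connectivity matches per-subject series correlation", {
  g <- box_grid(c(4L, 4L, 4L))
  set.seed(6)
  mats <- replicate(40, matrix(rnorm(64 * 50), nrow = 64), simplify = FALSE)
  conn <- fake_connectome(g, mats)
  ra <- array(FALSE, g$shape); ra[1:2, 1, 1] <- TRUE
  rb <- array(FALSE, g$shape); rb[3:4, 4, 4] <- TRUE
  r <- roi_to_roi_connectivity(conn, ra, rb)
  expect_length(r, 40)
  # identical ROIs correlate at exactly 1
  r_self <- roi_to_roi_connectivity(conn, ra, ra)
  expect_true(all(abs(r_self - 1) < 1e-12))
  # independent regions: mean r within 3 SE of 0
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(40))
  # zero-variance subjects are excluded and counted
  mats2 <- mats
  mats2[[1]][match(which(ra), g$mask_idx), ] <- 0
  r2 <- roi_to_roi_connectivity(fake_connectome(g, mats2), ra, rb)
  expect_length(r2, 39)
  expect_equal(attr(r2, "n_excluded"), 1)
})

test_that("network profile ANOVA matches sum-of-squares bookkeeping", {
  g <- box_grid(c(4L, 4L, 4L))
  set.seed(7)
  mats <- replicate(12, matrix(rnorm(64 * 40), nrow = 64), simplify = FALSE)
  conn <- fake_connectome(g, mats)
  seed_roi <- array(FALSE, g$shape); seed_roi[2, 2, 2] <- TRUE
  mk_roi <- function(i) { a <- array(FALSE, g$shape); a[i] <- TRUE; a }
  nets <- roi_set(g, list(n1 = mk_roi(40), n2 = mk_roi(50),
                          n3 = mk_roi(60)))
  res <- network_profile_anova(conn, list(seed_roi), nets)
  expect_equal(res$df, c(2, 12 * 3 - 3))
  # brute-force one-way ANOVA on the profile matrix
  y <- as.vector(res$profile)
  grp <- rep(1:3, each = 12)
  grand <- mean(y)
  ssb <- sum(tapply(y, grp, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum((y - ave(y, grp))^2)
  f_brute <- (ssb / 2) / (ssw / (36 - 3))
  expect_lt(abs(res$F - f_brute), 1e-8)

  # duplicated network: identical profiles give F ~ 0 for that contrast
  nets2 <- roi_set(g, list(a = mk_roi(40), b = mk_roi(40)))
  res2 <- network_profile_anova(conn, list(seed_roi), nets2)
  expect_lt(abs(res2$F), 1e-10)
  expect_error(network_profile_anova(conn, list(seed_roi),
                                     roi_set(g, list(only = mk_roi(40)))),
               "2 networks")
})

test_that("electrode montages rasterize into labelled scalp spheres", {
  g <- small_grid()
  tab <- electrode_positions_1020(g)
  expect_equal(nrow(tab), 19)
  expect_setequal(tab$label[1:3], c("Fp1", "Fp2", "F7"))
  rois <- electrode_spheres(tab, g, diameter_mm = 25)
  expect_length(rois$masks, 19)
  # sphere voxel counts match brute force
  for (nm in c("Cz", "O1")) {
    i <- match(nm, tab$label)
    ctr <- c(tab$x[i], tab$y[i], tab$z[i])
    d <- sqrt(colSums((t(g$coords_mm) - ctr)^2))
    expect_equal(sum(rois$masks[[nm]]), sum(d <= 12.5 + 1e-9 & g$mask))
  }
  # Cz sits above the mask centroid
  cz <- tab[tab$label == "Cz", ]
  expect_gt(cz$z, mean(g$coords_mm[g$mask_idx, 3]))
  # an electrode far outside the head errors with its label
  bad <- data.frame(label = "XX", x = 900, y = 0, z = 0)
  expect_error(electrode_spheres(bad, g), "XX")
})
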