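#' Average network overlap of an ROI, in percent
#'
#' The sum of the network map's values inside the mask, divided by the
#' number of voxels in the mask, times 100. Sign is preserved: an ROI
#' sitting on anticorrelated territory scores negative overlap.
#'
#' @param network_map a `stat_map`.
#' @param roi_mask nonempty logical array on the same grid.
#' @return overlap percentage (scalar).
#' @export
network_overlap_percent <- function(network_map, roi_mask) {
  stopifnot(identical(dim(roi_mask),
                      as.integer(network_map$grid$shape)))
  n <- sum(roi_mask)
  if (n == 0) stop("ROI mask is empty")
  100 * sum(network_map$values[roi_mask]) / n
}

#' Parcel-based null test for ROI overlap
#'
#' Compares the observed overlap of an ROI against a null distribution of
#' overlap values from parcels drawn uniformly with replacement from an
#' atlas-style parcellation. One-sided (greater):
#' `p = (1 + #{null >= observed}) / (1 + n_samples)`.
#'
#' @param network_map a `stat_map`.
#' @param roi_mask logical array, the observed ROI.
#' @param parcellation an `roi_set` with >= 2 parcels.
#' @param n_samples number of null draws (>= 100).
#' @param seed RNG seed.
#' @return list: `observed`, `p_value`, `null_mean`, `null_sd`,
#'   `n_samples`.
#' @export
parcel_null_test <- function(network_map, roi_mask, parcellation,
                             n_samples = 10000, seed = 1L) {
  stopifnot(length(parcellation$masks) >= 2)
  if (n_samples < 100) stop("n_samples must be >= 100")
  obs <- network_overlap_percent(network_map, roi_mask)
  parcel_overlap <- vapply(parcellation$masks, function(m)
    network_overlap_percent(network_map, m), numeric(1))
  set.seed(seed)
  null <- parcel_overlap[sample.int(length(parcel_overlap), n_samples,
                                    replace = TRUE)]
  list(observed = obs,
       p_value = (1 + sum(null >= obs)) / (1 + n_samples),
       null_mean = mean(null), null_sd = stats::sd(null),
       n_samples = n_samples)
}

#' Welch two-sample t-test on overlap scores
#'
#' Unequal-variance two-sided t-test with Welch-Satterthwaite degrees of
#' freedom and a 95% confidence interval for the mean difference. When
#' both groups are constant with equal means the result is `t = 0, p = 1`.
#'
#' @param scores_a,scores_b numeric vectors (>= 2 each).
#' @return list: `t`, `df`, `p`, `ci` (length 2), `mean_a`, `mean_b`.
#' @export
group_overlap_ttest <- function(scores_a, scores_b) {
  stopifnot(length(scores_a) >= 2, length(scores_b) >= 2)
  if (stats::sd(scores_a) == 0 && stats::sd(scores_b) == 0) {
    d <- mean(scores_a) - mean(scores_b)
    if (d == 0)
      return(list(t = 0, df = NA_real_, p = 1, ci = c(0, 0),
                  mean_a = mean(scores_a), mean_b = mean(scores_b)))
  }
  tt <- stats::t.test(scores_a, scores_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, ci = as.numeric(tt$conf.int),
       mean_a = mean(scores_a), mean_b = mean(scores_b))
}

#' Spatial correlation between two maps
#'
#' Pearson r over in-mask voxel pairs; the standard similarity measure
#' between whole-brain network maps.
#'
#' @param map_a,map_b `stat_map`s on the same grid.
#' @param mask optional logical array restricting the comparison (default:
#'   the grid's brain mask). Voxels that are non-finite in either map
#'   (e.g. the degenerate-variance sentinel inside a seed) are excluded.
#' @return Pearson r.
#' @export
spatial_correlation <- function(map_a, map_b, mask = NULL) {
  .check_same_grid(map_a$grid, map_b$grid)
  if (is.null(mask)) mask <- map_a$grid$mask
  mask <- mask & is.finite(map_a$values) & is.finite(map_b$values)
  a <- map_a$values[mask]
  b <- map_b$values[mask]
  if (length(a) < 3) stop("need at least 3 in-mask voxels")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("spatial correlation undefined for a constant map")
  stats::cor(a, b)
}

#' Per-subject ROI-to-ROI connectivity
#'
#' For each connectome subject, the Pearson correlation between the mean
#' time series of two ROIs. Subjects with a zero-variance ROI series are
#' excluded; the count of exclusions is reported in the `n_excluded`
#' attribute.
#'
#' @param connectome a `connectome`.
#' @param roi_a,roi_b nonempty logical arrays on the connectome's grid.
#' @return numeric vector of per-subject r values.
#' @export
roi_to_roi_connectivity <- function(connectome, roi_a, roi_b) {
  n <- n_subjects_conn(connectome)
  r <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    ta <- seed_timeseries(connectome, s, roi_a)
    tb <- seed_timeseries(connectome, s, roi_b)
    if (stats::sd(ta) == 0 || stats::sd(tb) == 0) next
    r[s] <- stats::cor(ta, tb)
  }
  out <- r[!is.na(r)]
  attr(out, "n_excluded") <- sum(is.na(r))
  out
}

#' Seed-to-network connectivity profile with one-way ANOVA
#'
#' For each subject and each named network, the mean ROI-to-ROI
#' connectivity between the seed ROIs and that network's ROIs, followed by
#' a one-way ANOVA across networks (subjects as observations, equal
#' variances, df = (k - 1, N - k)).
#'
#' @param connectome a `connectome`.
#' @param seed_rois list of logical arrays (e.g. study-level seeds).
#' @param network_rois an `roi_set` whose `groups` name the network of
#'   each ROI (default: each ROI is its own network).
#' @return list: `profile` (subjects x networks matrix of mean r),
#'   `means` (named per-network means), `F`, `df` (length 2), `p`,
#'   `argmax`, `argmin`.
#' @export
network_profile_anova <- function(connectome, seed_rois, network_rois) {
  groups <- network_rois$groups
  if (is.null(groups)) groups <- names(network_rois$masks)
  nets <- unique(groups)
  if (length(nets) < 2) stop("need at least 2 networks")
  n <- n_subjects_conn(connectome)
  prof <- matrix(NA_real_, nrow = n, ncol = length(nets),
                 dimnames = list(NULL, nets))
  for (s in seq_len(n)) {
    seed_ts <- lapply(seed_rois, function(m)
      seed_timeseries(connectome, s, m))
    roi_ts <- lapply(network_rois$masks, function(m)
      seed_timeseries(connectome, s, m))
    for (g in nets) {
      rs <- unlist(lapply(seed_ts, function(st)
        vapply(roi_ts[groups == g], function(rt) stats::cor(st, rt),
               numeric(1))))
      prof[s, g] <- mean(rs)
    }
  }
  y <- as.vector(prof)
  g <- factor(rep(nets, each = n), levels = nets)
  aovr <- stats::oneway.test(y ~ g, var.equal = TRUE)
  means <- colMeans(prof)
  list(profile = prof, means = means,
       F = unname(aovr$statistic),
       df = unname(c(aovr$parameter[1], aovr$parameter[2])),
       p = aovr$p.value,
       argmax = names(which.max(means)), argmin = names(which.min(means)))
}

#' Scalp-electrode sphere ROIs
#'
#' One binary sphere (default 25 mm diameter) per electrode, named by its
#' label. A sphere that covers no in-mask voxel is an error naming the
#' label.
#'
#' @param electrode_coordinate_table data frame with columns `label`, `x`,
#'   `y`, `z` (mm).
#' @param grid a `volume_grid`.
#' @param diameter_mm sphere diameter (default 25).
#' @return an `roi_set`, one ROI per electrode.
#' @export
electrode_spheres <- function(electrode_coordinate_table, grid,
                              diameter_mm = 25) {
  tab <- electrode_coordinate_table
  stopifnot(all(c("label", "x", "y", "z") %in% names(tab)), nrow(tab) >= 1)
  masks <- lapply(seq_len(nrow(tab)), function(i) {
    tryCatch(
      rasterize_sphere(grid, c(tab$x[i], tab$y[i], tab$z[i]), diameter_mm),
      error = function(e)
        stop("electrode '", tab$label[i], "': ", conditionMessage(e),
             call. = FALSE))
  })
  names(masks) <- tab$label
  roi_set(grid, masks)
}

#' Standard 10-20 electrode positions on a grid's scalp
#'
#' Places the 19 standard 10-20 montage labels on the brain-mask surface
#' by casting rays from the mask centroid along the montage's canonical
#' angles (inclination from vertex, azimuth from the anterior axis) and
#' taking the outermost in-mask point. This yields a montage scaled to any
#' head geometry, including the synthetic ellipsoid.
#'
#' @param grid a `volume_grid`.
#' @return data frame with columns `label`, `x`, `y`, `z`.
#' @export
electrode_positions_1020 <- function(grid) {
  ang <- data.frame(
    label = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
              "T3", "C3", "Cz", "C4", "T4",
              "T5", "P3", "Pz", "P4", "T6", "O1", "O2"),
    incl = c(90, 90, 90, 62, 45, 62, 90,
             90, 45, 0, 45, 90,
             90, 62, 45, 62, 90, 90, 90),
    azim = c(-18, 18, -54, -39, 0, 39, 54,
             -90, -90, 0, 90, 90,
             -126, -141, 180, 141, 126, -162, 162),
    stringsAsFactors = FALSE)
  ctr <- colMeans(grid$coords_mm[grid$mask_idx, , drop = FALSE])
  span <- max(grid$coords_mm[grid$mask_idx, ]) -
    min(grid$coords_mm[grid$mask_idx, ])
  pos <- t(vapply(seq_len(nrow(ang)), function(i) {
    th <- ang$incl[i] * pi / 180
    ph <- ang$azim[i] * pi / 180
    u <- c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
    ts <- seq(0, span, by = 1)
    pts <- outer(ts, u)
    pts <- sweep(pts, 2, ctr, "+")
    conv <- mm_to_voxel(grid, pts)
    inm <- conv$in_bounds
    inm[inm] <- grid$mask[.linear_index(grid, conv$ijk[inm, , drop = FALSE])]
    if (!any(inm)) return(ctr)
    pts[max(which(inm)), ]
  }, numeric(3)))
  data.frame(label = ang$label, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}
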