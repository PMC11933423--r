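#' Mean time series over a seed mask
#'
#' @param connectome a `connectome`.
#' @param subject subject index.
#' @param seed_mask logical array on the connectome's grid.
#' @return numeric vector of length `n_timepoints`: the unweighted mean of
#'   the in-seed voxel time series.
#' @export
seed_timeseries <- function(connectome, subject, seed_mask) {
  g <- connectome$grid
  stopifnot(identical(dim(seed_mask), as.integer(g$shape)))
  rows <- match(which(seed_mask & g$mask), g$mask_idx)
  rows <- rows[!is.na(rows)]
  if (length(rows) == 0)
    stop("seed mask has no voxels inside the data support")
  X <- subject_matrix(connectome, subject)
  colMeans(X[rows, , drop = FALSE])
}

# Pearson r of one series against every row of X; zero-variance rows -> 0.
# Returns vector with attribute n_zero_var.
.rowwise_cor <- function(X, s) {
  s_c <- s - mean(s)
  ss <- sqrt(sum(s_c^2))
  if (ss == 0) stop("seed time series has zero variance")
  X_c <- X - rowMeans(X)
  norms <- sqrt(rowSums(X_c^2))
  r <- as.numeric(X_c %*% s_c) / (norms * ss)
  zv <- norms == 0
  r[zv] <- 0
  attr(r, "n_zero_var") <- sum(zv)
  r
}

#' Seed-to-voxel connectivity map for one subject
#'
#' Pearson correlation between the seed-mean time series and every in-mask
#' voxel's series, optionally Fisher z-transformed (`atanh`, with |r|
#' clipped at `1 - 1e-7`). Zero-variance voxels are set to 0 and counted in
#' the `n_zero_var` attribute.
#'
#' @inheritParams seed_timeseries
#' @param fisher_z return Fisher z values (default `TRUE`) instead of raw r.
#' @return a `stat_map` of kind `"z"` (or `"r"`).
#' @export
seed_to_voxel_map <- function(connectome, subject, seed_mask,
                              fisher_z = TRUE) {
  s <- seed_timeseries(connectome, subject, seed_mask)
  X <- subject_matrix(connectome, subject)
  r <- .rowwise_cor(X, s)
  nzv <- attr(r, "n_zero_var")
  vals <- if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)) else r
  out <- stat_map(connectome$grid, as.numeric(vals),
                  kind = if (fisher_z) "z" else "r")
  out$n_zero_var <- nzv
  out
}

#' One-sample t-map across subjects
#'
#' Voxelwise one-sample t of the subject-level (Fisher z) connectivity
#' values against zero: `t = mean / (sd / sqrt(n))`. Voxels with zero
#' across-subject variance get a signed infinite sentinel (0 when the mean
#' is also 0) and are counted in `n_degenerate`.
#'
#' @param z_maps list of `stat_map`s (one per subject) on a shared grid, or
#'   a subjects x voxels numeric matrix paired with `grid`.
#' @param grid required when `z_maps` is a matrix.
#' @return a `stat_map` of kind `"t"`.
#' @export
group_t_map <- function(z_maps, grid = NULL) {
  if (is.matrix(z_maps)) {
    stopifnot(!is.null(grid))
    Z <- z_maps
  } else {
    stopifnot(length(z_maps) >= 3)
    grid <- z_maps[[1]]$grid
    for (m in z_maps[-1]) .check_same_grid(grid, m$grid)
    Z <- t(vapply(z_maps, mask_values, numeric(length(grid$mask_idx))))
  }
  n <- nrow(Z)
  if (n < 3) stop("group t-map needs at least 3 subjects")
  mu <- colMeans(Z)
  sd_v <- sqrt(colSums((Z - rep(mu, each = n))^2) / (n - 1))
  t_v <- mu / (sd_v / sqrt(n))
  degen <- sd_v == 0
  t_v[degen] <- sign(mu[degen]) * Inf
  t_v[degen & mu == 0] <- 0
  out <- stat_map(grid, as.numeric(t_v), kind = "t")
  out$n_degenerate <- sum(degen)
  out
}

#' Threshold a t-map into a signed ternary network
#'
#' `+1` where `t > threshold_t`, `-1` where `t < -threshold_t`, else `0`
#' (strict inequalities: a value exactly at the threshold maps to 0). The
#' default `threshold_t = 5.1` is the published voxelwise-FWE-equivalent
#' constant; the sensitivity set {4.7, 5.6, 7, 9} is accepted like any
#' other positive value.
#'
#' @param tmap a `stat_map` of kind `"t"`.
#' @param threshold_t positive threshold (default 5.1).
#' @param study_id optional study label carried on the result.
#' @return object of class `study_network`: `study_id`, `tmap`, `ternary`
#'   (a `stat_map` in {-1, 0, +1}), `threshold_t`.
#' @export
ternarize <- function(tmap, threshold_t = 5.1, study_id = NA_character_) {
  stopifnot(inherits(tmap, "stat_map"), threshold_t > 0)
  v <- tmap$values
  tern <- array(0, dim = dim(v))
  tern[v > threshold_t] <- 1
  tern[v < -threshold_t] <- -1
  structure(list(study_id = study_id, tmap = tmap,
                 ternary = stat_map(tmap$grid, tern, kind = "ternary"),
                 threshold_t = threshold_t),
            class = "study_network")
}

#' Overlap map across study networks
#'
#' The voxelwise mean of the signed ternary maps: the signed proportion of
#' studies whose network includes each voxel. Kept unthresholded — this is
#' the disease network map.
#'
#' @param study_networks list of `study_network`s on a shared grid.
#' @return a `stat_map` of kind `"overlap"` with an `n_studies` field;
#'   `values * n_studies` is an exact integer field.
#' @export
overlap_map <- function(study_networks) {
  stopifnot(length(study_networks) >= 1)
  grid <- study_networks[[1]]$ternary$grid
  acc <- array(0, dim = grid$shape)
  for (sn in study_networks) {
    .check_same_grid(grid, sn$ternary$grid, "study networks")
    acc <- acc + sn$ternary$values
  }
  out <- stat_map(grid, acc / length(study_networks), kind = "overlap")
  out$n_studies <- length(study_networks)
  out
}

#' Voxelwise-FWE-equivalent t threshold for a grid
#'
#' The Bonferroni two-sided t threshold at family-wise `p` over the in-mask
#' voxels, for reference when choosing `threshold_t` on other grids or
#' cohort sizes.
#'
#' @param n_subjects subjects entering the one-sample t-test.
#' @param n_voxels number of in-mask voxels.
#' @param p family-wise error rate (default 0.01).
#' @return the t threshold.
#' @export
fwe_t_threshold <- function(n_subjects, n_voxels, p = 0.01) {
  stats::qt(1 - p / (2 * n_voxels), df = n_subjects - 1)
}

#' Coordinate network mapping: per-study seed networks
#'
#' For each study (or each coordinate with `per_coordinate = TRUE`):
#' rasterize a sphere per focus, merge into the study-level seed, compute
#' per-subject seed-to-voxel Fisher-z maps across the connectome, the
#' group one-sample t-map, and the signed ternary network. Deterministic
#' given its inputs; row order of the coordinate table does not matter.
#'
#' @param coordinate_table a `coordinate_table`.
#' @param connectome a `connectome` with >= 3 subjects.
#' @param seed_diameter_mm seed sphere diameter (default 6; the published
#'   sensitivity set also used 3 and 9).
#' @param threshold_t ternarization threshold (default 5.1).
#' @param per_coordinate use each focus as its own seed instead of
#'   study-level unions (default `FALSE`).
#' @param fisher_z apply the Fisher z transform before the t-test
#'   (default `TRUE`).
#' @param snap_to_mask snap out-of-mask foci to the nearest in-mask voxel
#'   instead of erroring (default `FALSE`).
#' @return list of `study_network`s (one per study, or per coordinate).
#' @export
run_study_networks <- function(coordinate_table, connectome,
                               seed_diameter_mm = 6, threshold_t = 5.1,
                               per_coordinate = FALSE, fisher_z = TRUE,
                               snap_to_mask = FALSE) {
  stopifnot(nrow(coordinate_table) >= 1, n_subjects_conn(connectome) >= 3)
  g <- connectome$grid
  tab <- coordinate_table[order(coordinate_table$study_id), , drop = FALSE]
  units <- if (per_coordinate) {
    lapply(seq_len(nrow(tab)), function(i)
      list(id = sprintf("%s_f%03d", tab$study_id[i], i), rows = i))
  } else {
    ids <- unique(tab$study_id)
    lapply(ids, function(s) list(id = s, rows = which(tab$study_id == s)))
  }
  seeds <- lapply(units, function(u) {
    spheres <- lapply(u$rows, function(i) {
      tryCatch(
        rasterize_sphere(g, c(tab$x[i], tab$y[i], tab$z[i]),
                         seed_diameter_mm, snap_to_mask = snap_to_mask),
        error = function(e) stop("study '", u$id, "': ",
                                 conditionMessage(e), call. = FALSE))
    })
    combine_study_seed(spheres)
  })
  seed_rows <- lapply(seeds, function(m) match(which(m & g$mask), g$mask_idx))

  n_sub <- n_subjects_conn(connectome)
  nv <- length(g$mask_idx)
  zsum <- lapply(units, function(u) numeric(nv))
  zsq <- lapply(units, function(u) numeric(nv))
  for (s in seq_len(n_sub)) {
    X <- subject_matrix(connectome, s)
    X_c <- X - rowMeans(X)
    norms <- sqrt(rowSums(X_c^2))
    zv <- norms == 0
    for (ui in seq_along(units)) {
      st <- colMeans(X[seed_rows[[ui]], , drop = FALSE])
      st_c <- st - mean(st)
      ssn <- sqrt(sum(st_c^2))
      if (ssn == 0)
        stop("study '", units[[ui]]$id,
             "': seed time series has zero variance")
      r <- as.numeric(X_c %*% st_c) / (norms * ssn)
      r[zv] <- 0
      val <- if (fisher_z) atanh(pmin(pmax(r, -1 + 1e-7), 1 - 1e-7)) else r
      zsum[[ui]] <- zsum[[ui]] + val
      zsq[[ui]] <- zsq[[ui]] + val^2
    }
  }
  lapply(seq_along(units), function(ui) {
    mu <- zsum[[ui]] / n_sub
    var_v <- pmax(zsq[[ui]] / n_sub - mu^2, 0) * n_sub / (n_sub - 1)
    sd_v <- sqrt(var_v)
    t_v <- mu / (sd_v / sqrt(n_sub))
    degen <- sd_v == 0
    t_v[degen] <- sign(mu[degen]) * Inf
    t_v[degen & mu == 0] <- 0
    tmap <- stat_map(g, as.numeric(t_v), kind = "t")
    tmap$n_degenerate <- sum(degen)
    ternarize(tmap, threshold_t, study_id = units[[ui]]$id)
  })
}

#' Subset a coordinate table by metadata
#'
#' @param table a `coordinate_table`.
#' @param subtype,modality optional values to keep.
#' @param drop_subtype optional subtype to drop (leave-one-diagnosis-out).
#' @return the filtered `coordinate_table`.
#' @export
subset_coordinates <- function(table, subtype = NULL, modality = NULL,
                               drop_subtype = NULL) {
  keep <- rep(TRUE, nrow(table))
  if (!is.null(subtype)) keep <- keep & table$subtype %in% subtype
  if (!is.null(modality)) keep <- keep & table$modality %in% modality
  if (!is.null(drop_subtype)) keep <- keep & !(table$subtype %in% drop_subtype)
  out <- table[keep, , drop = FALSE]
  if (nrow(out) == 0) stop("subset leaves no coordinates")
  class(out) <- c("coordinate_table", "data.frame")
  out
}
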