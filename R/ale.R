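.fwhm_to_sigma <- function(fwhm_mm) fwhm_mm / (2 * sqrt(2 * log(2)))

# Max-update `ma` (full-grid numeric array) with a Gaussian kernel of
# amplitude `amp` centered at focus_mm, truncated at `cut_sd` standard
# deviations. Operates on a local voxel window for speed (axis-separable
# distances assume an orthogonal affine, which all package grids use).
.place_gaussian_max <- function(grid, ma, focus_mm, sigma, amp,
                                cut_sd = 3.5) {
  aff <- grid$affine
  vox_mm <- sqrt(colSums(aff[1:3, 1:3]^2))
  v <- grid$inv_affine[1:3, 1:3] %*% focus_mm + grid$inv_affine[1:3, 4]
  rad_vox <- ceiling(cut_sd * sigma / vox_mm)
  lo <- pmax(floor(v) - rad_vox, 0)
  hi <- pmin(ceiling(v) + rad_vox, grid$shape - 1L)
  if (any(lo > hi)) return(ma)
  ii <- lo[1]:hi[1]; jj <- lo[2]:hi[2]; kk <- lo[3]:hi[3]
  dx2 <- colSums((aff[1:3, 1:3] %*% rbind(ii - v[1], 0, 0))^2)
  dy2 <- colSums((aff[1:3, 1:3] %*% rbind(0, jj - v[2], 0))^2)
  dz2 <- colSums((aff[1:3, 1:3] %*% rbind(0, 0, kk - v[3]))^2)
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  kern <- amp * exp(-d2 / (2 * sigma^2))
  kern[d2 > (cut_sd * sigma)^2] <- 0
  nx <- grid$shape[1]; ny <- grid$shape[2]
  lin <- outer(outer(1L + ii, nx * jj, "+"), nx * ny * kk, "+")
  cur <- ma[lin]
  upd <- kern > cur
  if (any(upd)) ma[lin[upd]] <- kern[upd]
  ma
}

#' Modeled-activation (MA) map for one study
#'
#' Each focus contributes a 3-D Gaussian probability surface: the
#' isotropic Gaussian density of FWHM `fwhm_mm` centered on the focus,
#' scaled by the voxel volume so a voxel's value approximates the
#' probability mass it captures (maximum at the focus voxel; truncated at
#' 3.5 sd). The study's MA value at a voxel is the maximum across its
#' foci, so repeated foci within one study do not inflate the map. Foci
#' outside the grid bounds are skipped with a warning; a study whose foci
#' are all skipped is an error.
#'
#' @param grid a `volume_grid`.
#' @param study_foci n x 3 matrix of focus coordinates in mm.
#' @param fwhm_mm Gaussian kernel FWHM in mm (> 0; default 10).
#' @param study_id label carried on the result.
#' @return a `stat_map` of kind `"ale"` with fields `study_id`, `fwhm_mm`.
#' @export
modeled_activation <- function(grid, study_foci, fwhm_mm = 10,
                               study_id = NA_character_) {
  m <- if (is.matrix(study_foci)) study_foci else matrix(study_foci, ncol = 3)
  stopifnot(nrow(m) >= 1, fwhm_mm > 0)
  sigma <- .fwhm_to_sigma(fwhm_mm)
  vox_vol <- abs(det(grid$affine[1:3, 1:3]))
  amp <- vox_vol / ((2 * pi)^1.5 * sigma^3)
  ma <- array(0, dim = grid$shape)
  used <- 0L
  for (i in seq_len(nrow(m))) {
    conv <- mm_to_voxel(grid, m[i, ])
    if (!conv$in_bounds) {
      warning(sprintf("focus (%.1f, %.1f, %.1f) outside grid bounds; skipped",
                      m[i, 1], m[i, 2], m[i, 3]))
      next
    }
    ma <- .place_gaussian_max(grid, ma, as.numeric(m[i, ]), sigma, amp)
    used <- used + 1L
  }
  if (used == 0L) stop("all foci fell outside the grid")
  out <- stat_map(grid, ma, kind = "ale")
  out$study_id <- study_id
  out$fwhm_mm <- fwhm_mm
  out
}

#' ALE statistic across studies
#'
#' The voxelwise union of the modeled-activation maps:
#' `ALE(v) = 1 - prod_i (1 - MA_i(v))`, in `[0, 1)`.
#'
#' @param ma_maps list of MA `stat_map`s on a shared grid.
#' @return a `stat_map` of kind `"ale"`.
#' @export
ale_statistic <- function(ma_maps) {
  stopifnot(length(ma_maps) >= 1)
  grid <- ma_maps[[1]]$grid
  acc <- array(1, dim = grid$shape)
  for (m in ma_maps) {
    .check_same_grid(grid, m$grid, "MA maps")
    acc <- acc * (1 - m$values)
  }
  stat_map(grid, 1 - acc, kind = "ale")
}

# 26-connected component labelling of a logical 3-D array.
# Returns integer array of labels (0 = background).
.label_components_26 <- function(mask_arr) {
  dims <- dim(mask_arr)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  lab <- array(0L, dim = dims)
  idx <- which(mask_arr)
  if (length(idx) == 0) return(lab)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  in_set <- array(FALSE, dim = dims)
  in_set[idx] <- TRUE
  cur <- 0L
  for (v in idx) {
    if (lab[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    lab[v] <- cur
    while (length(queue) > 0) {
      q <- queue
      queue <- integer(0)
      q0 <- q - 1L
      i <- q0 %% nx
      j <- (q0 %/% nx) %% ny
      k <- q0 %/% (nx * ny)
      for (o in seq_len(nrow(off))) {
        ni <- i + off[o, 1]; nj <- j + off[o, 2]; nk <- k + off[o, 3]
        ok <- ni >= 0L & ni < nx & nj >= 0L & nj < ny & nk >= 0L & nk < nz
        if (!any(ok)) next
        nl <- 1L + ni[ok] + nx * (nj[ok] + ny * nk[ok])
        nl <- nl[in_set[nl] & lab[nl] == 0L]
        if (length(nl) > 0) {
          lab[nl] <- cur
          queue <- c(queue, nl)
        }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' ALE permutation null and cluster-FWE thresholding
#'
#' Per permutation, each study's foci are redistributed uniformly over the
#' in-mask voxel centers and the ALE map is recomputed. The voxel-level
#' null (pooled over permutations and in-mask voxels) sets the
#' cluster-forming ALE threshold at `1 - cluster_forming_p`; the null of
#' maximum 26-connected cluster sizes sets the cluster-level FWE size
#' threshold at `1 - cluster_fwe_p`. Clusters of the observed map
#' exceeding that size are retained.
#'
#' @param coordinate_table a `coordinate_table` of observed foci.
#' @param grid a `volume_grid`.
#' @param n_permutations number of permutations (>= 100).
#' @param cluster_forming_p voxel-level cluster-forming p (default 0.001).
#' @param cluster_fwe_p cluster-level FWE p (default 0.01).
#' @param fwhm_mm kernel FWHM in mm: a scalar, or a function of a study's
#'   `n_patients` returning the FWHM (default constant 10).
#' @param seed RNG seed.
#' @return list with `ale` (observed `stat_map`), `cluster_map` (integer
#'   labels of surviving clusters as a `stat_map`), `clusters` (data frame:
#'   `cluster`, `n_voxels`, `peak_x/y/z` mm, `peak_ale`), `ale_threshold`,
#'   `size_threshold`, `n_permutations`, `seed`.
#' @export
ale_null_threshold <- function(coordinate_table, grid, n_permutations,
                               cluster_forming_p = 0.001,
                               cluster_fwe_p = 0.01, fwhm_mm = 10,
                               seed = 1L) {
  if (n_permutations < 100)
    stop("n_permutations must be >= 100")
  tab <- coordinate_table
  ids <- unique(tab$study_id)
  fwhm_of <- if (is.function(fwhm_mm)) fwhm_mm else function(n) fwhm_mm
  study_fwhm <- vapply(ids, function(s) {
    np <- tab$n_patients[tab$study_id == s][1]
    as.numeric(fwhm_of(if (is.na(np)) NA else np))
  }, numeric(1))
  study_counts <- vapply(ids, function(s) sum(tab$study_id == s), integer(1))

  ale_from_foci <- function(foci_by_study) {
    mas <- lapply(seq_along(ids), function(si)
      modeled_activation(grid, foci_by_study[[si]], study_fwhm[si],
                         study_id = ids[si]))
    ale_statistic(mas)
  }
  obs_foci <- lapply(ids, function(s)
    as.matrix(tab[tab$study_id == s, c("x", "y", "z")]))
  obs <- ale_from_foci(obs_foci)

  set.seed(seed)
  nv <- length(grid$mask_idx)
  perm_vals <- matrix(0, nrow = n_permutations, ncol = nv)
  for (p in seq_len(n_permutations)) {
    rf <- lapply(seq_along(ids), function(si) {
      v <- grid$mask_idx[sample.int(nv, study_counts[si], replace = TRUE)]
      grid$coords_mm[v, , drop = FALSE]
    })
    perm_vals[p, ] <- mask_values(ale_from_foci(rf))
  }
  ale_thr <- stats::quantile(perm_vals, 1 - cluster_forming_p, names = FALSE)
  max_sizes <- vapply(seq_len(n_permutations), function(p) {
    supra <- array(FALSE, dim = grid$shape)
    supra[grid$mask_idx[perm_vals[p, ] > ale_thr]] <- TRUE
    lab <- .label_components_26(supra)
    if (max(lab) == 0L) 0L else max(tabulate(lab[lab > 0L]))
  }, integer(1))
  size_thr <- stats::quantile(max_sizes, 1 - cluster_fwe_p, names = FALSE)

  supra <- obs$values > ale_thr & grid$mask
  lab <- .label_components_26(supra)
  keep <- integer(0)
  if (max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes > size_thr)
  }
  out_lab <- array(0L, dim = grid$shape)
  rows <- list()
  for (ci in seq_along(keep)) {
    vox <- which(lab == keep[ci])
    out_lab[vox] <- ci
    pk <- vox[which.max(obs$values[vox])]
    ijk <- arrayInd(pk, grid$shape) - 1L
    mm <- voxel_to_mm(grid, ijk)
    rows[[ci]] <- data.frame(cluster = ci, n_voxels = length(vox),
                             peak_x = mm[1], peak_y = mm[2], peak_z = mm[3],
                             peak_ale = obs$values[pk])
  }
  clusters <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cluster = integer(0), n_voxels = integer(0),
               peak_x = numeric(0), peak_y = numeric(0),
               peak_z = numeric(0), peak_ale = numeric(0))
  cmap <- stat_map(grid, array(as.numeric(out_lab), dim = grid$shape),
                   kind = "weighted")
  list(ale = obs, cluster_map = cmap, clusters = clusters,
       ale_threshold = ale_thr, size_threshold = size_thr,
       n_permutations = n_permutations, seed = seed)
}
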