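#' Random-coordinate control study sets
#'
#' Redistributes each study's foci uniformly over the in-mask voxel
#' centers, `n_repeats` times, preserving per-study focus counts. With 21
#' input studies and 4 repeats this yields 84 random study-level
#' coordinate sets, the published control construction.
#'
#' @param coordinate_table a `coordinate_table`.
#' @param grid a `volume_grid` supplying the brain mask.
#' @param n_repeats number of repeats (>= 1).
#' @param seed RNG seed.
#' @return a `coordinate_table` with `n_studies(table) * n_repeats`
#'   studies; metadata columns are carried over from the source study.
#' @export
random_coordinate_sets <- function(coordinate_table, grid, n_repeats,
                                   seed = 1L) {
  stopifnot(n_repeats >= 1)
  set.seed(seed)
  nv <- length(grid$mask_idx)
  out <- list()
  for (r in seq_len(n_repeats)) {
    for (s in unique(coordinate_table$study_id)) {
      sub <- coordinate_table[coordinate_table$study_id == s, , drop = FALSE]
      v <- grid$mask_idx[sample.int(nv, nrow(sub), replace = TRUE)]
      mm <- grid$coords_mm[v, , drop = FALSE]
      sub$x <- mm[, 1]; sub$y <- mm[, 2]; sub$z <- mm[, 3]
      sub$study_id <- sprintf("%s_rand%d", s, r)
      out[[length(out) + 1L]] <- as.data.frame(sub)
    }
  }
  as_coordinate_table(do.call(rbind, out))
}

# Welch t for two row-stacked matrices (subjects x voxels)
.welch_t_rows <- function(A, B) {
  na <- nrow(A); nb <- nrow(B)
  mua <- colMeans(A); mub <- colMeans(B)
  va <- colSums((A - rep(mua, each = na))^2) / (na - 1)
  vb <- colSums((B - rep(mub, each = nb))^2) / (nb - 1)
  se <- sqrt(va / na + vb / nb)
  t_v <- (mua - mub) / se
  t_v[se == 0 & mua == mub] <- 0
  t_v
}

# Signed TFCE transform of a voxel vector on a grid (26-connectivity).
.tfce_vector <- function(vals, grid, H = 2, E = 0.5, n_steps = 20) {
  out <- numeric(length(vals))
  for (sgn in c(1, -1)) {
    v <- sgn * vals
    vmax <- max(v)
    if (vmax <= 0) next
    dh <- vmax / n_steps
    hs <- seq(dh / 2, vmax - dh / 2, by = dh)
    acc <- numeric(length(vals))
    for (h in hs) {
      supra <- array(FALSE, dim = grid$shape)
      supra[grid$mask_idx[v > h]] <- TRUE
      lab <- .label_components_26(supra)
      labv <- lab[grid$mask_idx]
      sel <- labv > 0L
      if (!any(sel)) next
      ext <- tabulate(labv[sel])
      acc[sel] <- acc[sel] + ext[labv[sel]]^E * h^H * dh
    }
    out <- out + sgn * acc
  }
  out
}

#' Voxelwise two-sample permutation test with FDR control
#'
#' Observed statistic: unequal-variance (Welch) two-sample t per in-mask
#' voxel. The null is built by permuting group labels; per voxel,
#' `p = (1 + #{|t_perm| >= |t_obs|}) / (1 + n_permutations)` (two-sided),
#' then Benjamini-Hochberg adjusted across in-mask voxels. Optionally the
#' t-maps are TFCE-transformed (default H = 2, E = 0.5, 26-connectivity)
#' before ranking.
#'
#' @param networks_a,networks_b lists of `stat_map`s (>= 3 each) on a
#'   shared grid; typically unthresholded study t-maps. The same map
#'   object must not appear in both groups.
#' @param n_permutations number of label permutations (>= 100).
#' @param alpha FDR significance level for `sig_mask` (default 0.05).
#' @param tfce apply TFCE before ranking (default `FALSE`).
#' @param tfce_h,tfce_e TFCE height and extent exponents.
#' @param method `"random"` label permutations (default) or
#'   `"exhaustive"`, which enumerates every group assignment (including
#'   the observed one; feasible only for small groups). Exhaustive p-values
#'   are `#\{|t_perm| >= |t_obs|\} / n_assignments` and are exactly
#'   invariant under swapping the groups.
#' @param seed RNG seed.
#' @return object of class `voxelwise_test`: `tmap`, `pmap` (uncorrected),
#'   `qmap` (FDR), `sig_mask` (logical array, q < alpha), `alpha`,
#'   `n_permutations`, `seed`.
#' @export
two_sample_permutation_test <- function(networks_a, networks_b,
                                        n_permutations, alpha = 0.05,
                                        tfce = FALSE, tfce_h = 2,
                                        tfce_e = 0.5,
                                        method = c("random", "exhaustive"),
                                        seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(networks_a) >= 3, length(networks_b) >= 3)
  if (method == "random" && n_permutations < 100)
    stop("n_permutations must be >= 100")
  for (ma in networks_a) for (mb in networks_b)
    if (identical(ma, mb))
      stop("the same map appears in both groups")
  grid <- networks_a[[1]]$grid
  nv <- length(grid$mask_idx)
  A <- t(vapply(networks_a, mask_values, numeric(nv)))
  B <- t(vapply(networks_b, mask_values, numeric(nv)))
  for (m in c(networks_a[-1], networks_b)) .check_same_grid(grid, m$grid)
  na <- nrow(A); nb <- nrow(B)
  M <- rbind(A, B)

  stat_of <- function(lab_a) {
    t_v <- .welch_t_rows(M[lab_a, , drop = FALSE],
                         M[-lab_a, , drop = FALSE])
    if (tfce) .tfce_vector(t_v, grid, H = tfce_h, E = tfce_e) else t_v
  }
  t_obs <- stat_of(seq_len(na))
  if (method == "exhaustive") {
    combos <- utils::combn(na + nb, na, simplify = FALSE)
    exceed <- numeric(nv)
    for (lab in combos)
      exceed <- exceed + (abs(stat_of(lab)) >= abs(t_obs))
    p_v <- exceed / length(combos)
    n_permutations <- length(combos)
  } else {
    set.seed(seed)
    exceed <- numeric(nv)
    for (p in seq_len(n_permutations)) {
      lab <- sample.int(na + nb, na)
      exceed <- exceed + (abs(stat_of(lab)) >= abs(t_obs))
    }
    p_v <- (1 + exceed) / (1 + n_permutations)
  }
  q_v <- stats::p.adjust(p_v, method = "BH")
  sig <- array(FALSE, dim = grid$shape)
  sig[grid$mask_idx[q_v < alpha]] <- TRUE
  raw_t <- .welch_t_rows(A, B)
  structure(list(tmap = stat_map(grid, as.numeric(raw_t), kind = "t"),
                 pmap = stat_map(grid, as.numeric(p_v), kind = "pvalue"),
                 qmap = stat_map(grid, as.numeric(q_v), kind = "pvalue"),
                 sig_mask = sig, alpha = alpha,
                 n_permutations = n_permutations, seed = seed,
                 tfce = tfce),
            class = "voxelwise_test")
}

#' @export
print.voxelwise_test <- function(x, ...) {
  q <- mask_values(x$qmap)
  cat(sprintf(
    "<voxelwise_test> %d permutations; %d/%d voxels significant at q<%.2f\n",
    x$n_permutations, sum(x$sig_mask), length(q), x$alpha))
  invisible(x)
}
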