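#' Clinical outcome summary of a stimulated cohort
#'
#' Summarizes `%` seizure-frequency reduction outcomes: median, quartiles
#' (linear interpolation between order statistics; `quantile_type = 7`),
#' mean, standard error (`sd / sqrt(n)`), and responders — patients with
#' outcome strictly greater than the threshold (default 50%).
#'
#' @param patients list of `stim_patient`s, or a numeric vector of
#'   outcome percentages.
#' @param responder_threshold_pct responder cut (strict `>`; default 50).
#' @param quantile_type quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return object of class `outcome_summary`: `n`, `median`, `q25`, `q75`,
#'   `mean`, `se`, `responder_count`, `responder_rate`.
#' @export
outcome_stats <- function(patients, responder_threshold_pct = 50,
                          quantile_type = 7) {
  x <- if (is.numeric(patients)) patients
       else vapply(patients, function(p) p$outcome_pct, numeric(1))
  x <- x[is.finite(x)]
  if (length(x) == 0) stop("no finite outcomes")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = quantile_type,
                       names = FALSE)
  resp <- sum(x > responder_threshold_pct)
  structure(list(n = length(x), median = q[2], q25 = q[1], q75 = q[3],
                 mean = mean(x), se = stats::sd(x) / sqrt(length(x)),
                 responder_count = resp,
                 responder_rate = resp / length(x)),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf(
    paste0("<outcome_summary> n=%d; median %.1f%% (IQR %.1f-%.1f),",
           " mean %.1f%% (SE %.1f); %d/%d responders (%.0f%%)\n"),
    x$n, x$median, x$q25, x$q75, x$mean, x$se,
    x$responder_count, x$n, 100 * x$responder_rate))
  invisible(x)
}

# group t-map of connectivity to a single seed across the connectome
.seed_group_tmap <- function(connectome, seed_mask, fisher_z = TRUE) {
  n <- n_subjects_conn(connectome)
  g <- connectome$grid
  nv <- length(g$mask_idx)
  Z <- matrix(0, nrow = n, ncol = nv)
  for (s in seq_len(n)) {
    Z[s, ] <- mask_values(seed_to_voxel_map(connectome, s, seed_mask,
                                            fisher_z = fisher_z))
  }
  group_t_map(Z, grid = g)
}

#' Stimulation-site (VAT) network
#'
#' The group connectivity t-map of a patient's stimulation volume,
#' computed with the same machinery as a study-level coordinate network:
#' per-subject seed-to-voxel Fisher-z maps across the normative
#' connectome, then a one-sample t-test.
#'
#' @param patient a `stim_patient` (or a bare logical VAT mask).
#' @param connectome a `connectome`.
#' @param fisher_z apply the Fisher z transform (default `TRUE`).
#' @return a `stat_map` of kind `"t"`.
#' @export
vat_network <- function(patient, connectome, fisher_z = TRUE) {
  vat <- if (inherits(patient, "stim_patient")) patient$vat else patient
  if (!any(vat)) stop("VAT mask is empty")
  .seed_group_tmap(connectome, vat, fisher_z = fisher_z)
}

#' Outcome-weighted average network
#'
#' `W(v) = sum_i w_i M_i(v) / sum_i w_i` with `w_i` the patients' clinical
#' outcomes (% seizure-frequency reduction), used as raw percentages.
#' Individual negative weights (worsened patients) are allowed, but the
#' total weight must be positive.
#'
#' @param patient_maps list of `stat_map`s on a shared grid.
#' @param outcomes numeric weights, one per map.
#' @return a `stat_map` of kind `"weighted"`.
#' @export
weighted_average_network <- function(patient_maps, outcomes) {
  stopifnot(length(patient_maps) >= 1,
            length(outcomes) == length(patient_maps),
            all(is.finite(outcomes)))
  if (sum(outcomes) <= 0)
    stop("degenerate weighting: total outcome weight must be positive")
  grid <- patient_maps[[1]]$grid
  acc <- array(0, dim = grid$shape)
  for (i in seq_along(patient_maps)) {
    .check_same_grid(grid, patient_maps[[i]]$grid, "patient maps")
    acc <- acc + outcomes[i] * patient_maps[[i]]$values
  }
  stat_map(grid, acc / sum(outcomes), kind = "weighted")
}

#' Convergent network from two maps
#'
#' Each map is z-scored within the mask (mean 0, sd 1) and the two are
#' averaged. The construction is symmetric: the result correlates equally
#' with either input on the same mask.
#'
#' @param map_a,map_b `stat_map`s on the same grid, nonconstant in the
#'   mask.
#' @param mask optional logical array (default: the grid's brain mask).
#'   Voxels non-finite in either map are excluded (left 0).
#' @return a `stat_map` of kind `"weighted"` with in-mask mean 0.
#' @export
convergent_network <- function(map_a, map_b, mask = NULL) {
  .check_same_grid(map_a$grid, map_b$grid)
  grid <- map_a$grid
  if (is.null(mask)) mask <- grid$mask
  mask <- mask & is.finite(map_a$values) & is.finite(map_b$values)
  zs <- function(m) {
    v <- m$values[mask]
    if (stats::sd(v) == 0) stop("constant map: cannot z-score")
    (v - mean(v)) / stats::sd(v)
  }
  out <- array(0, dim = grid$shape)
  out[mask] <- (zs(map_a) + zs(map_b)) / 2
  stat_map(grid, out, kind = "weighted")
}

#' Peak voxel of a map within a region
#'
#' The argmax of the map over the region (intersected with the brain
#' mask), in mm via the grid affine. Ties break to the lowest linear
#' voxel index.
#'
#' @param map a `stat_map`.
#' @param region_mask optional logical array (default: whole brain mask).
#' @return list: `mm` (length-3), `value`, `ijk` (0-based).
#' @export
peak_voxel <- function(map, region_mask = NULL) {
  grid <- map$grid
  region <- if (is.null(region_mask)) grid$mask else region_mask & grid$mask
  vox <- which(region)
  if (length(vox) == 0) stop("peak region is empty")
  best <- vox[which.max(map$values[vox])]
  ijk <- arrayInd(best, grid$shape) - 1L
  list(mm = as.numeric(voxel_to_mm(grid, ijk)),
       value = map$values[best], ijk = as.integer(ijk))
}

#' Euclidean distance between two mm coordinates
#' @param coord_a,coord_b numeric length-3 mm coordinates.
#' @return distance in mm.
#' @export
peak_distance_mm <- function(coord_a, coord_b) {
  stopifnot(all(is.finite(coord_a)), all(is.finite(coord_b)))
  sqrt(sum((as.numeric(coord_a) - as.numeric(coord_b))^2))
}

#' Stimulation-cohort network (outcome-weighted)
#'
#' Convenience wrapper: computes each patient's VAT network and the
#' outcome-weighted average across the cohort.
#'
#' @param patients list of `stim_patient`s.
#' @param connectome a `connectome`.
#' @return list: `network` (weighted `stat_map`), `patient_maps`,
#'   `outcomes`.
#' @export
dbs_cohort_network <- function(patients, connectome) {
  maps <- lapply(patients, vat_network, connectome = connectome)
  outcomes <- vapply(patients, function(p) p$outcome_pct, numeric(1))
  list(network = weighted_average_network(maps, outcomes),
       patient_maps = maps, outcomes = outcomes)
}

#' Synthetic 21-patient stimulation outcome cohort
#'
#' A synthetic stand-in for a centromedian-DBS cohort's seizure-frequency
#' outcomes, constructed to be consistent with the published cohort
#' summary (n = 21; median 90%, interquartile range 66.5-96.5%; mean
#' 66.7%, standard error 14.3; 19/21 responders at the >50% rule). The
#' individual values are synthetic; only the summary statistics are
#' anchored. Shipped as
#' `inst/extdata/synthetic_cm_dbs_outcomes.tsv`.
#'
#' @return data frame with columns `patient_id`, `outcome_pct`.
#' @export
synthetic_dbs_outcomes <- function() {
  path <- system.file("extdata", "synthetic_cm_dbs_outcomes.tsv",
                      package = "coordnet", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Read a stimulation-patient manifest
#'
#' TSV with columns `patient_id`, `vat_path` (NIfTI mask, relative to the
#' manifest directory unless absolute), `outcome_pct`.
#'
#' @param path manifest path.
#' @param grid `volume_grid` the VAT masks must match.
#' @return list of `stim_patient`s.
#' @export
read_patient_manifest <- function(path, grid) {
  man <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "vat_path", "outcome_pct") %in% names(man)))
  base <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$vat_path[i]
    if (!grepl("^/", p)) p <- file.path(base, p)
    vat <- read_volume(p, grid = grid)$values != 0
    if (!any(vat)) stop("empty VAT mask for patient ", man$patient_id[i])
    structure(list(patient_id = as.character(man$patient_id[i]),
                   vat = vat, outcome_pct = man$outcome_pct[i]),
              class = "stim_patient")
  })
}
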