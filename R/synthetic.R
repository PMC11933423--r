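#' Planted-network model for synthetic connectomes
#'
#' Builds K spatial components on a grid. Component 1 is the planted
#' "disease network": a signed topography with positive lobes (a compact
#' subcortical blob emulating a thalamic hub plus superior sensorimotor-like
#' blobs) and negative lobes (frontal-pole and posterior blobs), emulating
#' the anticorrelated organisation typical of seed-based disease networks.
#' Remaining components are smooth random background networks. Subject time
#' series are later generated as loading-weighted mixtures of component
#' time courses plus voxelwise white noise.
#'
#' @param grid a `volume_grid` (default [default_grid()]).
#' @param k number of components (>= 1; default 4).
#' @param timecourse_sd per-component time-course standard deviation
#'   (scalar or length-k; default 1).
#' @param noise_sd voxelwise noise standard deviation (default 1).
#' @param seed RNG seed for the background components.
#' @return object of class `planted_network_model` with fields
#'   `grid`, `components` (list of loading arrays in \[-1, 1\]),
#'   `thalamus_mask` (the subcortical positive blob at >= half maximum),
#'   `timecourse_sd`, `noise_sd`, `seed`.
#' @export
planted_network_model <- function(grid = default_grid(), k = 4,
                                  timecourse_sd = 1, noise_sd = 1,
                                  seed = 42L) {
  stopifnot(k >= 1, noise_sd >= 0)
  timecourse_sd <- rep_len(timecourse_sd, k)
  ext <- apply(grid$coords_mm[grid$mask_idx, , drop = FALSE], 2, range)
  span <- ext[2, ] - ext[1, ]
  ctr <- colMeans(ext)

  blob <- function(center, sigma_mm, amp) {
    d2 <- colSums((t(grid$coords_mm) - center)^2)
    amp * exp(-d2 / (2 * sigma_mm^2))
  }
  # disease component: signed lobes placed relative to the mask extent
  thal_center <- ctr + c(-0.08, -0.15, -0.05) * span
  pos <- blob(thal_center, 7, 1) +
    blob(ctr + c(-0.22, 0.02, 0.30) * span, 8, 0.9) +
    blob(ctr + c(0.22, 0.02, 0.30) * span, 8, 0.9) +
    blob(ctr + c(0, -0.32, -0.22) * span, 7, 0.8)
  neg <- blob(ctr + c(0, 0.38, 0.10) * span, 8, 0.9) +
    blob(ctr + c(0, -0.38, 0.25) * span, 8, 0.9) +
    blob(ctr + c(-0.30, 0.15, -0.05) * span, 7, 0.7) +
    blob(ctr + c(0.30, 0.15, -0.05) * span, 7, 0.7)
  disease <- pmin(pmax(pos - neg, -1), 1)
  disease[!grid$mask] <- 0

  thal_field <- blob(thal_center, 7, 1)
  thalamus <- array(thal_field >= 0.5 & grid$mask, dim = grid$shape)

  set.seed(seed)
  components <- vector("list", k)
  components[[1]] <- array(disease, dim = grid$shape)
  if (k > 1) {
    for (j in 2:k) {
      f <- numeric(nrow(grid$coords_mm))
      for (b in 1:8) {
        cen <- ext[1, ] + stats::runif(3) * span
        f <- f + blob(cen, stats::runif(1, 6, 10),
                      stats::runif(1, 0.4, 0.8) * sample(c(-1, 1), 1))
      }
      f <- f / max(abs(f))
      f[!grid$mask] <- 0
      components[[j]] <- array(f, dim = grid$shape)
    }
  }
  structure(list(grid = grid, components = components,
                 thalamus_mask = thalamus, thal_center = thal_center,
                 timecourse_sd = timecourse_sd, noise_sd = noise_sd,
                 seed = seed),
            class = "planted_network_model")
}

#' Planted disease-network map
#' @param model a `planted_network_model`.
#' @return the disease component as a `stat_map` (kind `"weighted"`).
#' @export
disease_component <- function(model)
  stat_map(model$grid, model$components[[1]], kind = "weighted")

#' Generate a synthetic subject-level connectome
#'
#' Each subject's in-mask voxel-by-time matrix is
#' `X = L %*% C + noise_sd * E` where `L` are the model's component
#' loadings, `C` are subject-specific i.i.d. Gaussian component time
#' courses (scaled by `timecourse_sd`), and `E` is i.i.d. Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param model a `planted_network_model`.
#' @param n_subjects number of subjects (>= 2).
#' @param n_timepoints time points per subject (>= 10).
#' @param seed RNG seed.
#' @return object of class `connectome`: list with `grid`, `subjects`
#'   (list of in-mask voxel x time matrices), `n_timepoints`.
#' @export
generate_connectome <- function(model, n_subjects, n_timepoints, seed = 1L) {
  stopifnot(inherits(model, "planted_network_model"),
            n_subjects >= 2, n_timepoints >= 10)
  L <- vapply(model$components, function(a) a[model$grid$mask_idx],
              numeric(length(model$grid$mask_idx)))
  if (all(L == 0)) stop("degenerate model: all component loadings are zero")
  set.seed(seed)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    C <- matrix(stats::rnorm(ncol(L) * n_timepoints, sd = model$timecourse_sd),
                nrow = ncol(L), byrow = FALSE)
    X <- L %*% C
    if (model$noise_sd > 0)
      X <- X + matrix(stats::rnorm(length(X), sd = model$noise_sd),
                      nrow = nrow(X))
    subjects[[s]] <- X
  }
  structure(list(grid = model$grid, subjects = subjects,
                 n_timepoints = n_timepoints),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %d subjects, %d voxels x %d timepoints\n",
              n_subjects_conn(x), length(x$grid$mask_idx), x$n_timepoints))
  invisible(x)
}

#' Number of subjects in a connectome
#' @param connectome a `connectome`.
#' @return integer.
#' @export
n_subjects_conn <- function(connectome) length(connectome$subjects)

#' Fetch one subject's voxel x time matrix
#'
#' Subjects stored as file paths (see [write_connectome()]) are loaded on
#' demand, one at a time, so peak memory does not grow with the cohort.
#'
#' @param connectome a `connectome`.
#' @param i subject index.
#' @return numeric matrix, in-mask voxels x time.
#' @export
subject_matrix <- function(connectome, i) {
  s <- connectome$subjects[[i]]
  if (is.character(s)) {
    arr <- as.array(RNifti::readNifti(s))
    stopifnot(length(dim(arr)) == 4)
    mat <- matrix(arr, nrow = prod(dim(arr)[1:3]))[connectome$grid$mask_idx, ,
                                                   drop = FALSE]
    return(mat)
  }
  s
}

#' Write / read a connectome as per-subject 4-D NIfTI volumes
#'
#' @param connectome a `connectome` (in memory).
#' @param dir output directory; one `sub-XXX.nii.gz` per subject plus a
#'   `connectome.json` manifest.
#' @return `write_connectome`: the directory, invisibly.
#'   `read_connectome`: a lazy `connectome` whose subjects are loaded on
#'   demand.
#' @export
write_connectome <- function(connectome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- connectome$grid
  files <- character(n_subjects_conn(connectome))
  for (i in seq_len(n_subjects_conn(connectome))) {
    X <- subject_matrix(connectome, i)
    arr <- array(0, dim = c(g$shape, ncol(X)))
    flat <- matrix(arr, nrow = prod(g$shape))
    flat[g$mask_idx, ] <- X
    arr <- array(flat, dim = c(g$shape, ncol(X)))
    img <- RNifti::asNifti(arr, datatype = "float")
    RNifti::sform(img) <- structure(g$affine, code = 2L)
    files[i] <- sprintf("sub-%03d.nii.gz", i)
    RNifti::writeNifti(img, file.path(dir, files[i]))
  }
  jsonlite::write_json(list(n_subjects = n_subjects_conn(connectome),
                            n_timepoints = connectome$n_timepoints,
                            files = files),
                       file.path(dir, "connectome.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_connectome
#' @param grid the `volume_grid` the stored volumes must match.
#' @export
read_connectome <- function(dir, grid) {
  man <- jsonlite::read_json(file.path(dir, "connectome.json"),
                             simplifyVector = TRUE)
  structure(list(grid = grid,
                 subjects = as.list(file.path(dir, man$files)),
                 n_timepoints = man$n_timepoints),
            class = "connectome")
}

#' Sample study-tagged abnormality coordinates from the planted network
#'
#' Foci are drawn from in-mask voxels whose planted disease loading exceeds
#' a quantile cutoff (by default the positive lobe only; see Details), with
#' Gaussian mm jitter, plus a stated fraction of uniformly placed
#' off-network foci. Study metadata (subtype, modality, sample sizes) are
#' assigned from the supplied vectors, recycled across studies.
#'
#' @details With `mode = "positive"` candidates are voxels whose loading
#'   exceeds the `cutoff_quantile` of in-mask loadings; with
#'   `mode = "absolute"` the cutoff is applied to |loading|, drawing from
#'   both lobes. Abnormality foci in the emulated literature fall
#'   predominantly in positively connected territory, and seeds in the
#'   anticorrelated lobe produce sign-flipped networks, so `"positive"` is
#'   the default.
#'
#' @param model a `planted_network_model`.
#' @param n_studies number of studies (>= 1).
#' @param foci_per_study_range integer length-2 range of foci per study
#'   (inclusive), or use `foci_counts` for exact per-study counts.
#' @param foci_counts optional integer vector of per-study focus counts
#'   (overrides the range).
#' @param jitter_mm standard deviation of isotropic Gaussian jitter added
#'   to each sampled voxel center (mm).
#' @param frac_offnetwork fraction of foci placed uniformly over the brain
#'   mask instead of the network (default 0.2).
#' @param n_thalamic exact number of foci constrained to lie inside the
#'   model's subcortical (thalamus-analogue) mask; the remaining foci are
#'   constrained to lie outside it. Default 0 (no constraint).
#' @param mode `"positive"` or `"absolute"` candidate selection.
#' @param cutoff_quantile quantile of the loading distribution defining
#'   on-network candidate voxels (default 0.85).
#' @param subtypes,modalities character vectors recycled over studies.
#' @param n_patients,n_controls integer vectors recycled over studies.
#' @param seed RNG seed.
#' @return a `coordinate_table`.
#' @export
sample_study_coordinates <- function(model, n_studies,
                                     foci_per_study_range = c(4L, 10L),
                                     foci_counts = NULL,
                                     jitter_mm = 2,
                                     frac_offnetwork = 0.2,
                                     n_thalamic = 0L,
                                     mode = c("positive", "absolute"),
                                     cutoff_quantile = 0.85,
                                     subtypes = "mixed",
                                     modalities = "atrophy",
                                     n_patients = 25L,
                                     n_controls = 35L,
                                     seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(n_studies >= 1, frac_offnetwork >= 0, frac_offnetwork <= 1)
  g <- model$grid
  loading <- model$components[[1]][g$mask_idx]
  score <- if (mode == "positive") loading else abs(loading)
  cutoff <- stats::quantile(score, cutoff_quantile)
  candidates <- g$mask_idx[score > cutoff]
  if (length(candidates) == 0)
    stop("loading cutoff leaves no candidate voxels")
  thal_lin <- which(model$thalamus_mask)
  cand_thal <- intersect(candidates, thal_lin)
  if (n_thalamic > 0 && length(cand_thal) == 0)
    stop("no on-network candidate voxels inside the thalamic mask")

  set.seed(seed)
  counts <- if (!is.null(foci_counts)) {
    stopifnot(length(foci_counts) == n_studies)
    as.integer(foci_counts)
  } else {
    sample(foci_per_study_range[1]:foci_per_study_range[2], n_studies,
           replace = TRUE)
  }
  total <- sum(counts)
  stopifnot(n_thalamic <= total)
  # mark which foci (global order) must land in the thalamic mask
  thal_flag <- rep(FALSE, total)
  if (n_thalamic > 0)
    thal_flag[sample.int(total, n_thalamic)] <- TRUE

  draw_focus <- function(must_thal) {
    # rejection-sample so the thalamic membership survives the jitter
    for (attempt in 1:200) {
      off <- !must_thal && stats::runif(1) < frac_offnetwork
      pool <- if (must_thal) cand_thal
              else if (off) g$mask_idx
              else candidates
      v <- pool[sample.int(length(pool), 1)]
      mm <- g$coords_mm[v, ] + stats::rnorm(3, sd = jitter_mm)
      conv <- mm_to_voxel(g, mm)
      if (!conv$in_bounds) next
      if (!g$mask[.linear_index(g, conv$ijk)]) next
      if (n_thalamic == 0) return(mm)
      in_thal <- model$thalamus_mask[.linear_index(g, conv$ijk)]
      if (in_thal == must_thal) return(mm)
    }
    stop("could not place focus respecting the thalamic constraint")
  }

  rows <- vector("list", n_studies)
  pos <- 1L
  for (s in seq_len(n_studies)) {
    k <- counts[s]
    mm <- t(vapply(thal_flag[pos:(pos + k - 1L)], draw_focus, numeric(3)))
    pos <- pos + k
    rows[[s]] <- data.frame(
      study_id = sprintf("study_%02d", s),
      x = mm[, 1], y = mm[, 2], z = mm[, 3],
      modality = rep_len(modalities, n_studies)[s],
      subtype = rep_len(subtypes, n_studies)[s],
      n_patients = rep_len(as.integer(n_patients), n_studies)[s],
      n_controls = rep_len(as.integer(n_controls), n_studies)[s],
      stringsAsFactors = FALSE)
  }
  as_coordinate_table(do.call(rbind, rows))
}

#' Synthetic study table emulating the published IGE literature
#'
#' A fixed preset of 21 studies contributing 131 foci (540 patients, 778
#' controls across studies; 8 GTCS, 7 JME, 2 AE and 4 mixed-subtype
#' studies; 13 atrophy and 8 fMRI-hyperactivity studies), with exactly 22
#' foci (17%) inside the model's thalamic mask.
#'
#' @param model a `planted_network_model`.
#' @param seed RNG seed.
#' @return a `coordinate_table` with 131 rows from 21 studies.
#' @export
synth_ige_coordinates <- function(model, seed = 7L) {
  foci <- c(9L, 5L, 7L, 6L, 4L, 8L, 6L, 5L, 7L, 6L,
            10L, 5L, 6L, 7L, 4L, 6L, 8L, 5L, 6L, 5L, 6L)
  npat <- c(30L, 22L, 25L, 28L, 20L, 35L, 24L, 18L, 26L, 27L,
            31L, 21L, 23L, 29L, 19L, 33L, 26L, 22L, 28L, 25L, 28L)
  nctl <- c(40L, 30L, 35L, 38L, 28L, 45L, 34L, 26L, 36L, 37L,
            41L, 31L, 33L, 39L, 29L, 43L, 36L, 32L, 38L, 35L, 72L)
  subtype <- c(rep("GTCS", 8), rep("JME", 7), rep("AE", 2), rep("mixed", 4))
  modality <- c(rep("atrophy", 13), rep("hyperactivity", 8))
  sample_study_coordinates(model, n_studies = 21L, foci_counts = foci,
                           jitter_mm = 2, frac_offnetwork = 0.2,
                           n_thalamic = 22L,
                           subtypes = subtype, modalities = modality,
                           n_patients = npat, n_controls = nctl,
                           seed = seed)
}

#' Random Voronoi parcellation of the brain mask
#'
#' Partitions the in-mask voxels into `n_parcels` parcels by assigning each
#' voxel to its nearest of `n_parcels` seeded random centers (mm distance;
#' ties to the first center). Parcels are disjoint, nonempty, and cover the
#' mask — a stand-in for an anatomical atlas in parcel-based null models.
#'
#' @param grid a `volume_grid`.
#' @param n_parcels number of parcels (>= 2, <= in-mask voxel count).
#' @param seed RNG seed.
#' @return an `roi_set` of `n_parcels` parcels.
#' @export
generate_parcellation <- function(grid, n_parcels, seed = 1L) {
  nv <- length(grid$mask_idx)
  stopifnot(n_parcels >= 2, n_parcels <= nv)
  set.seed(seed)
  centers <- grid$mask_idx[sample.int(nv, n_parcels)]
  cmm <- grid$coords_mm[centers, , drop = FALSE]
  vm <- grid$coords_mm[grid$mask_idx, , drop = FALSE]
  # nearest-center assignment, chunked over centers to bound memory
  best_d <- rep(Inf, nv)
  assign <- integer(nv)
  for (p in seq_len(n_parcels)) {
    d <- (vm[, 1] - cmm[p, 1])^2 + (vm[, 2] - cmm[p, 2])^2 +
      (vm[, 3] - cmm[p, 3])^2
    upd <- d < best_d
    best_d[upd] <- d[upd]
    assign[upd] <- p
  }
  masks <- lapply(seq_len(n_parcels), function(p) {
    m <- array(FALSE, dim = grid$shape)
    m[grid$mask_idx[assign == p]] <- TRUE
    m
  })
  names(masks) <- sprintf("parcel_%03d", seq_len(n_parcels))
  roi_set(grid, masks)
}

#' Synthetic stimulated patients with planted outcome structure
#'
#' Places spherical stimulation volumes (VATs) near the subcortical peak of
#' the planted disease network with positional scatter, and assigns each
#' patient an outcome `%` reduction = `outcome_gain` x (mean disease
#' loading inside the VAT) + Gaussian noise, truncated at 100.
#'
#' @param model a `planted_network_model`.
#' @param n_patients number of patients (>= 2).
#' @param vat_radius_mm VAT sphere radius in mm (default 2).
#' @param outcome_gain gain mapping loading to % outcome (default 95).
#' @param outcome_noise_sd outcome noise sd in % points (default 10).
#' @param scatter_mm positional scatter (sd, mm) of VAT centers around the
#'   subcortical peak (default 4).
#' @param seed RNG seed.
#' @return list of `stim_patient` objects: `patient_id`, `vat`
#'   (logical array), `outcome_pct`.
#' @export
generate_stim_patients <- function(model, n_patients, vat_radius_mm = 2,
                                   outcome_gain = 95, outcome_noise_sd = 10,
                                   scatter_mm = 4, seed = 1L) {
  stopifnot(n_patients >= 2)
  g <- model$grid
  disease <- model$components[[1]]
  thal_vals <- disease[g$mask_idx]
  peak_lin <- g$mask_idx[which.max(thal_vals *
                                     model$thalamus_mask[g$mask_idx])]
  peak_mm <- g$coords_mm[peak_lin, ]
  set.seed(seed)
  out <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    ctr <- peak_mm + stats::rnorm(3, sd = scatter_mm)
    vat <- rasterize_sphere(g, ctr, 2 * vat_radius_mm, snap_to_mask = TRUE)
    load_mean <- mean(disease[vat])
    outc <- outcome_gain * load_mean +
      if (outcome_noise_sd > 0) stats::rnorm(1, sd = outcome_noise_sd) else 0
    out[[i]] <- structure(list(patient_id = sprintf("pt_%02d", i),
                               vat = vat,
                               outcome_pct = min(outc, 100)),
                          class = "stim_patient")
  }
  out
}

#' Write a provenance manifest for a synthetic dataset
#' @param path output JSON path.
#' @param params named list of generator parameters and seeds.
#' @export
write_synth_manifest <- function(path, params) {
  jsonlite::write_json(params, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
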