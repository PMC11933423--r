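#' Voxel grid geometry
#'
#' A `volume_grid` holds the lattice geometry shared by every map in an
#' analysis: the array shape, the 4x4 voxel-to-mm affine, and a brain mask.
#' Voxel indices are 0-based in the public interface; mm coordinates follow
#' the RAS convention of the affine.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric voxel-to-mm transform; must be invertible.
#' @param mask logical array of dimension `shape` (default: all `TRUE`).
#'   Must contain at least one `TRUE` voxel.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine, mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 100)
    stop("grid affine is not invertible")
  if (is.null(mask)) mask <- array(TRUE, dim = shape)
  stopifnot(identical(dim(mask), as.integer(shape)), is.logical(mask))
  if (!any(mask)) stop("brain mask is empty")

  inv_affine <- solve(affine)
  # precompute mm coordinates of every voxel center (0-based indices)
  ijk <- as.matrix(expand.grid(i = 0:(shape[1] - 1L),
                               j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  coords_mm <- t(affine[1:3, 1:3] %*% t(ijk) + affine[1:3, 4])
  g <- list(shape = shape, affine = affine, inv_affine = inv_affine,
            mask = mask, mask_idx = which(mask), coords_mm = coords_mm)
  class(g) <- "volume_grid"
  g
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %s voxels, %.3g mm^3/voxel, %d in mask\n",
              paste(x$shape, collapse = "x"),
              abs(det(x$affine[1:3, 1:3])), length(x$mask_idx)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param grid a `volume_grid`.
#' @return integer count.
#' @export
n_mask_voxels <- function(grid) length(grid$mask_idx)

#' Default synthetic analysis grid
#'
#' A desk-scale stand-in for a standard-space brain volume: 24x28x24 voxels
#' at 3 mm isotropic with an ellipsoidal brain mask, mm origin at the grid
#' center so coordinates span roughly -35..35 mm per axis.
#'
#' @param shape grid shape (default `c(24, 28, 24)`).
#' @param voxel_mm isotropic voxel size in mm (default 3).
#' @return a `volume_grid`.
#' @export
default_grid <- function(shape = c(24L, 28L, 24L), voxel_mm = 3) {
  shape <- as.integer(shape)
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2
  ctr <- (shape - 1) / 2
  semi <- (shape - 2) / 2
  ijk <- expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                     k = 0:(shape[3] - 1L))
  r2 <- ((ijk$i - ctr[1]) / semi[1])^2 + ((ijk$j - ctr[2]) / semi[2])^2 +
    ((ijk$k - ctr[3]) / semi[3])^2
  mask <- array(r2 <= 1, dim = shape)
  volume_grid(shape, affine, mask)
}

#' Convert mm coordinates to voxel indices
#'
#' Applies the inverse affine and rounds to the nearest lattice point.
#' Out-of-bounds results are flagged, not errors.
#'
#' @param grid a `volume_grid`.
#' @param coord_mm numeric vector of length 3, or an n x 3 matrix.
#' @return a list with `ijk` (0-based integer indices, n x 3 matrix) and
#'   `in_bounds` (logical vector).
#' @export
mm_to_voxel <- function(grid, coord_mm) {
  m <- if (is.matrix(coord_mm)) coord_mm else matrix(coord_mm, ncol = 3)
  stopifnot(ncol(m) == 3, all(is.finite(m)))
  v <- t(grid$inv_affine[1:3, 1:3] %*% t(m) + grid$inv_affine[1:3, 4])
  ijk <- round(v)
  storage.mode(ijk) <- "integer"
  in_bounds <- ijk[, 1] >= 0L & ijk[, 1] < grid$shape[1] &
    ijk[, 2] >= 0L & ijk[, 2] < grid$shape[2] &
    ijk[, 3] >= 0L & ijk[, 3] < grid$shape[3]
  list(ijk = ijk, in_bounds = in_bounds)
}

#' Convert voxel indices to mm coordinates
#' @param grid a `volume_grid`.
#' @param ijk 0-based integer indices, length 3 or n x 3 matrix.
#' @return n x 3 matrix of mm coordinates.
#' @export
voxel_to_mm <- function(grid, ijk) {
  m <- if (is.matrix(ijk)) ijk else matrix(ijk, ncol = 3)
  t(grid$affine[1:3, 1:3] %*% t(m) + grid$affine[1:3, 4])
}

# 1-based linear array index from 0-based ijk matrix
.linear_index <- function(grid, ijk) {
  1L + ijk[, 1] + grid$shape[1] * (ijk[, 2] + grid$shape[2] * ijk[, 3])
}

#' Test whether two grids share geometry
#' @param a,b `volume_grid` objects.
#' @return `TRUE` if shape, affine and mask agree.
#' @export
same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$affine, b$affine, tolerance = 1e-10)) &&
    identical(a$mask, b$mask)
}

.check_same_grid <- function(a, b, what = "maps") {
  if (!same_grid(a, b)) stop("grid mismatch between ", what)
}

#' Rasterize a sphere onto the grid
#'
#' A voxel is included iff its center lies within `diameter_mm / 2` of
#' `center_mm` (closed ball). The result is intersected with the brain
#' mask; by default an empty intersection is an error naming the
#' coordinate, with `snap_to_mask = TRUE` the center is first moved to the
#' nearest in-mask voxel center.
#'
#' @param grid a `volume_grid`.
#' @param center_mm sphere center in mm (length 3).
#' @param diameter_mm sphere diameter in mm (>= 0; 0 keeps only a voxel
#'   whose center coincides with `center_mm`).
#' @param snap_to_mask move the center to the nearest in-mask voxel center
#'   before rasterizing (default `FALSE`).
#' @return logical array of the grid's shape.
#' @export
rasterize_sphere <- function(grid, center_mm, diameter_mm,
                             snap_to_mask = FALSE) {
  stopifnot(length(center_mm) == 3, all(is.finite(center_mm)),
            diameter_mm >= 0)
  center_mm <- as.numeric(center_mm)
  if (snap_to_mask) {
    d2m <- colSums((t(grid$coords_mm[grid$mask_idx, , drop = FALSE]) -
                      center_mm)^2)
    center_mm <- grid$coords_mm[grid$mask_idx[which.min(d2m)], ]
  }
  r <- diameter_mm / 2
  d2 <- colSums((t(grid$coords_mm) - center_mm)^2)
  sel <- d2 <= r^2 + 1e-9
  out <- array(sel & grid$mask, dim = grid$shape)
  if (!any(out))
    stop(sprintf("sphere at (%.1f, %.1f, %.1f) mm covers no in-mask voxel",
                 center_mm[1], center_mm[2], center_mm[3]))
  out
}

#' Union of sphere masks into a study-level seed
#'
#' Coordinates reported by one study are not independent, so their spheres
#' are merged into a single seed by set union.
#'
#' @param sphere_masks list of logical arrays on the same grid.
#' @return logical array, the voxelwise union.
#' @export
combine_study_seed <- function(sphere_masks) {
  stopifnot(length(sphere_masks) >= 1)
  dims <- dim(sphere_masks[[1]])
  out <- sphere_masks[[1]]
  for (m in sphere_masks[-1]) {
    if (!identical(dim(m), dims)) stop("grid mismatch between sphere masks")
    out <- out | m
  }
  out
}

#' Voxelwise scalar map on a grid
#'
#' @param grid a `volume_grid`.
#' @param values numeric array of the grid's shape, or a vector over
#'   in-mask voxels (expanded to the full array, 0 elsewhere).
#' @param kind one of `"r"`, `"z"`, `"t"`, `"ternary"`, `"overlap"`,
#'   `"ale"`, `"pvalue"`, `"weighted"`.
#' @return object of class `stat_map`; values outside the mask are 0.
#' @export
stat_map <- function(grid, values,
                     kind = c("r", "z", "t", "ternary", "overlap", "ale",
                              "pvalue", "weighted")) {
  kind <- match.arg(kind)
  if (is.null(dim(values))) {
    stopifnot(length(values) == length(grid$mask_idx))
    full <- array(0, dim = grid$shape)
    full[grid$mask_idx] <- values
    values <- full
  } else {
    stopifnot(identical(dim(values), as.integer(grid$shape)))
    values[!grid$mask] <- 0
  }
  if (kind == "ternary" &&
      !all(values %in% c(-1, 0, 1)))
    stop("ternary map values must be in {-1, 0, +1}")
  if (kind %in% c("overlap", "r") && max(abs(values)) > 1 + 1e-12)
    stop(sprintf("%s map values must lie in [-1, 1]", kind))
  structure(list(grid = grid, values = values, kind = kind),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- mask_values(x)
  cat(sprintf("<stat_map kind=%s> range [%.4g, %.4g] over %d voxels\n",
              x$kind, min(v), max(v), length(v)))
  invisible(x)
}

#' In-mask values of a map
#' @param map a `stat_map`.
#' @return numeric vector over in-mask voxels (fixed grid ordering).
#' @export
mask_values <- function(map) map$values[map$grid$mask_idx]

#' Named set of binary ROIs on a shared grid
#'
#' @param grid a `volume_grid`.
#' @param masks named list of logical arrays (each nonempty, same shape).
#' @param groups optional character vector of group labels, one per ROI.
#' @return object of class `roi_set`.
#' @export
roi_set <- function(grid, masks, groups = NULL) {
  stopifnot(length(masks) >= 1, !is.null(names(masks)),
            !anyDuplicated(names(masks)))
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!identical(dim(m), as.integer(grid$shape)))
      stop("ROI '", nm, "' is not on the shared grid")
    if (!any(m)) stop("ROI '", nm, "' is empty")
  }
  if (!is.null(groups)) stopifnot(length(groups) == length(masks))
  structure(list(grid = grid, masks = masks, groups = groups),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set> %d ROIs on %s grid\n", length(x$masks),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}
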