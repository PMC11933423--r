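#' Read a coordinate table of neuroimaging foci
#'
#' Expects a delimited text file with one row per reported focus and at
#' least the columns `study`, `x`, `y`, `z` (mm, standard space). Optional
#' columns: `modality` (`atrophy`/`hyperactivity`), `subtype` (`GTCS`,
#' `JME`, `AE`, `mixed`), `n_patients`, `n_controls`. Unknown modality or
#' subtype strings map to `"unknown"`.
#'
#' @param path file path.
#' @param dialect `"tsv"`, `"csv"`, or `"auto"` (default; decided by file
#'   extension, falling back to tab).
#' @return a `data.frame` of class `coordinate_table` with columns
#'   `study_id`, `x`, `y`, `z`, `modality`, `subtype`, `n_patients`,
#'   `n_controls`.
#' @export
read_coordinate_table <- function(path, dialect = c("auto", "tsv", "csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("coordinate table not found: ", path)
  sep <- switch(dialect,
                tsv = "\t", csv = ",",
                auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) ","
                       else "\t")
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  if (nrow(df) == 0) stop("coordinate table has no rows: ", path)
  names(df)[names(df) == "study"] <- "study_id"
  required <- c("study_id", "x", "y", "z")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("coordinate table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  for (cc in c("x", "y", "z")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- !is.finite(v)
    if (any(bad))
      stop(sprintf("non-numeric %s coordinate in study '%s' (row %d)",
                   cc, df$study_id[which(bad)[1]], which(bad)[1]))
    df[[cc]] <- v
  }
  as_coordinate_table(df)
}

#' Construct a coordinate table from a data frame
#'
#' @param df data frame with columns `study_id` (or `study`), `x`, `y`,
#'   `z`, and optionally `modality`, `subtype`, `n_patients`, `n_controls`.
#' @return a validated `coordinate_table`.
#' @export
as_coordinate_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df)[names(df) == "study"] <- "study_id"
  stopifnot(all(c("study_id", "x", "y", "z") %in% names(df)),
            nrow(df) >= 1)
  df$study_id <- as.character(df$study_id)
  if (any(!nzchar(df$study_id)) || anyNA(df$study_id))
    stop("every focus needs a study_id")
  if (!all(is.finite(as.matrix(df[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  known_mod <- c("atrophy", "hyperactivity")
  known_sub <- c("GTCS", "JME", "AE", "mixed")
  df$modality <- if ("modality" %in% names(df))
    ifelse(df$modality %in% known_mod, df$modality, "unknown")
  else "unknown"
  df$subtype <- if ("subtype" %in% names(df))
    ifelse(df$subtype %in% known_sub, df$subtype, "unknown")
  else "unknown"
  for (cc in c("n_patients", "n_controls")) {
    if (!cc %in% names(df)) df[[cc]] <- NA_integer_
    df[[cc]] <- as.integer(df[[cc]])
  }
  if (any(!is.na(df$n_patients) & df$n_patients < 1))
    stop("n_patients must be >= 1 where present")
  df <- df[, c("study_id", "x", "y", "z", "modality", "subtype",
               "n_patients", "n_controls")]
  class(df) <- c("coordinate_table", "data.frame")
  df
}

#' @export
print.coordinate_table <- function(x, ...) {
  cat(sprintf("<coordinate_table> %d foci from %d studies\n",
              n_rows(x), n_studies(x)))
  NextMethod()
}

#' Count studies / foci in a coordinate table
#' @param table a `coordinate_table`.
#' @return integer.
#' @export
n_studies <- function(table) length(unique(table$study_id))

#' @rdname n_studies
#' @export
n_rows <- function(table) nrow(table)

#' Write a coordinate table as TSV
#' @param table a `coordinate_table`.
#' @param path output path.
#' @export
write_coordinate_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a NIfTI volume as a stat map
#'
#' @param path NIfTI-1 file (.nii or .nii.gz).
#' @param grid optional `volume_grid` the volume must match (shape and
#'   affine); a mismatch is an error. When omitted, a grid with an
#'   all-`TRUE` mask is built from the file header.
#' @param kind map kind passed to [stat_map()].
#' @return a `stat_map`.
#' @export
read_volume <- function(path, grid = NULL, kind = "weighted") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3)
    stop("expected a 3-D volume, got ", length(dim(arr)), "-D: ", path)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  if (!is.null(grid)) {
    if (!identical(as.integer(dim(arr)), grid$shape))
      stop("volume shape does not match expected grid: ", path)
    if (!isTRUE(all.equal(aff, grid$affine, tolerance = 1e-5)))
      stop("volume affine does not match expected grid: ", path)
    return(stat_map(grid, arr, kind = kind))
  }
  stat_map(volume_grid(dim(arr), aff), arr, kind = kind)
}

#' Write a stat map (or mask) as NIfTI
#'
#' The grid affine is stored in the sform/qform; a write-read round trip
#' preserves values to storage precision and the affine exactly.
#'
#' @param map a `stat_map`, or a logical array paired with `grid`.
#' @param path output path (.nii or .nii.gz).
#' @param grid required when `map` is a bare array.
#' @export
write_volume <- function(map, path, grid = NULL) {
  if (inherits(map, "stat_map")) {
    arr <- map$values
    grid <- map$grid
  } else {
    stopifnot(!is.null(grid))
    arr <- array(as.numeric(map), dim = grid$shape)
  }
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an ROI set from a manifest
#'
#' The manifest is a TSV with columns `name`, `path` (NIfTI mask, relative
#' to the manifest's directory unless absolute) and optionally `group`.
#'
#' @param manifest_path path to the manifest TSV.
#' @param grid `volume_grid` all masks must match.
#' @return an `roi_set`.
#' @export
read_roi_set <- function(manifest_path, grid) {
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("name", "path") %in% names(man)), nrow(man) >= 1)
  base <- dirname(manifest_path)
  masks <- lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!grepl("^/", p)) p <- file.path(base, p)
    m <- read_volume(p, grid = grid)
    m$values != 0
  })
  names(masks) <- man$name
  roi_set(grid, masks, groups = if ("group" %in% names(man)) man$group)
}

#' Write an ROI set as NIfTI masks plus a manifest
#' @param rois an `roi_set`.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_roi_set <- function(rois, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(rois$masks))
  for (i in seq_along(rois$masks)) {
    paths[i] <- paste0(names(rois$masks)[i], ".nii.gz")
    write_volume(rois$masks[[i]], file.path(dir, paths[i]), grid = rois$grid)
  }
  man <- data.frame(name = names(rois$masks), path = paths,
                    stringsAsFactors = FALSE)
  if (!is.null(rois$groups)) man$group <- rois$groups
  manifest <- file.path(dir, "manifest.tsv")
  utils::write.table(man, manifest, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(manifest)
}
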