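#' Read a 4D-flow velocity dataset from NIfTI component volumes
#'
#' Each velocity component is one NIfTI file holding a 4-D array with the
#' cardiac frame as the fourth dimension. All components must share grid
#' shape and voxel spacing; a mismatch is an error naming the offending
#' file, never a silent resample. Stored values are converted to cm/s by
#' `scale` (e.g. `0.1` when integers encode mm/s).
#'
#' @param component_paths Character length-3, paths to the x, y and z
#'   component volumes (in grid-axis order).
#' @param rr_interval Cardiac cycle duration in seconds.
#' @param venc Optional velocity-encoding limit in cm/s.
#' @param scale Multiplicative factor taking stored values to cm/s.
#' @param magnitude_path Optional path to a magnitude volume on the same
#'   grid.
#' @return A [velocity_field()].
#' @export
read_velocity_series <- function(component_paths, rr_interval, venc = NULL,
                                 scale = 1, magnitude_path = NULL) {
  if (length(component_paths) != 3) {
    stop("`component_paths` must name exactly three component volumes",
         call. = FALSE)
  }
  vols <- lapply(component_paths, read_nifti_4d)
  ref_dim <- dim(vols[[1]]$data); ref_sp <- vols[[1]]$spacing
  for (i in 2:3) {
    if (!identical(dim(vols[[i]]$data), ref_dim)) {
      stop("component file '", component_paths[[i]], "' has shape ",
           paste(dim(vols[[i]]$data), collapse = "x"),
           " but '", component_paths[[1]], "' has ",
           paste(ref_dim, collapse = "x"), call. = FALSE)
    }
    if (!isTRUE(all.equal(vols[[i]]$spacing, ref_sp, tolerance = 1e-6))) {
      stop("component file '", component_paths[[i]],
           "' has voxel spacing ", paste(vols[[i]]$spacing, collapse = "x"),
           " mm, mismatching '", component_paths[[1]], "'", call. = FALSE)
    }
  }
  magnitude <- NULL
  if (!is.null(magnitude_path)) {
    mg <- read_nifti_4d(magnitude_path)
    if (!identical(dim(mg$data), ref_dim)) {
      stop("magnitude file '", magnitude_path, "' does not share the ",
           "velocity grid", call. = FALSE)
    }
    magnitude <- mg$data
  }
  velocity_field(vols[[1]]$data * scale, vols[[2]]$data * scale,
                 vols[[3]]$data * scale,
                 spacing = ref_sp, rr_interval = rr_interval, venc = venc,
                 magnitude = magnitude)
}

read_nifti_4d <- function(path) {
  if (!file.exists(path)) stop("file not found: '", path, "'", call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- unclass(img)
  attributes(a) <- attributes(a)["dim"]
  if (length(dim(a)) == 3) dim(a) <- c(dim(a), 1L)
  if (length(dim(a)) != 4) {
    stop("'", path, "' is not a 3-D/4-D volume (found ",
         length(dim(a)), " dimensions)", call. = FALSE)
  }
  list(data = a, spacing = as.numeric(RNifti::pixdim(img)[1:3]))
}

#' Write a velocity field as NIfTI component volumes
#'
#' Inverse of [read_velocity_series()]: one file per component
#' (`<prefix>_vx.nii.gz` etc.), double precision so round trips are
#' bit-exact.
#'
#' @param field A [velocity_field()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the written paths, invisibly usable
#'   directly as `component_paths`.
#' @export
write_velocity_series <- function(field, dir, prefix = "velocity") {
  stopifnot(inherits(field, "velocity_field"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comps <- c(vx = "vx", vy = "vy", vz = "vz")
  paths <- vapply(comps, function(cmp) {
    p <- file.path(dir, paste0(prefix, "_", cmp, ".nii.gz"))
    write_nifti_4d(field[[cmp]], field$spacing,
                   field$rr_interval / field$n_frames, p)
    p
  }, character(1))
  if (!is.null(field$magnitude)) {
    p <- file.path(dir, paste0(prefix, "_mag.nii.gz"))
    write_nifti_4d(field$magnitude, field$spacing,
                   field$rr_interval / field$n_frames, p)
    paths <- c(paths, magnitude = p)
  }
  invisible(paths)
}

write_nifti_4d <- function(a, spacing, dt, path) {
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- c(spacing, dt)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a time-resolved binary LV mask from NIfTI
#'
#' Voxel values other than 0/1 are rejected (a fractional or multi-label
#' segmentation is not silently thresholded), as is any frame with an
#' empty cavity.
#'
#' @param path NIfTI file with the 4-D mask.
#' @inheritParams cine_mask
#' @return A [cine_mask()].
#' @export
read_mask_series <- function(path, slice_axis = 3L, apex_to_base_sign = 1L) {
  vol <- read_nifti_4d(path)
  bad <- setdiff(unique(as.vector(vol$data)), c(0, 1))
  if (length(bad) > 0) {
    stop("mask file '", path, "' contains non-binary value(s) ",
         paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
  }
  cine_mask(vol$data, slice_axis = slice_axis,
            apex_to_base_sign = apex_to_base_sign, spacing = vol$spacing)
}

#' Write a cine mask as NIfTI
#' @param seg A [cine_mask()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_mask_series <- function(seg, path) {
  stopifnot(inherits(seg, "cine_mask"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  write_nifti_4d(seg$mask + 0, seg$spacing, 1, path)
  invisible(path)
}

#' Write cohort result tables to CSV
#'
#' Writes the per-subject flow-parameter table and any accompanying
#' cohort-level tables (group effects, demographics, correlations) as
#' full-precision CSV files.
#'
#' @param records Tibble of per-subject records (one row per subject).
#' @param tables Named list of additional tibbles, e.g.
#'   `list(group_effects = ..., demographics = ..., correlations = ...)`.
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of written paths.
#' @export
write_results <- function(records, tables = list(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(records) == 0) {
    warning("empty cohort: writing header-only subject table", call. = FALSE)
  }
  paths <- c(subjects = file.path(out_dir, "subjects.csv"))
  readr::write_csv(records, paths[["subjects"]])
  for (nm in names(tables)) {
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], p)
    paths[nm] <- p
  }
  paths
}

#' Read back result tables written by [write_results()]
#' @param out_dir Directory holding the CSV files.
#' @return Named list of tibbles, one per CSV file found.
#' @export
read_results <- function(out_dir) {
  files <- list.files(out_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no result tables under '", out_dir, "'", call. = FALSE)
  out <- lapply(files, readr::read_csv, show_col_types = FALSE)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Read a run configuration from YAML or JSON
#' @param path Configuration file (`.yaml`/`.yml` or `.json`).
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}
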