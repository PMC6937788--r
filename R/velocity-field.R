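#' Time-resolved three-directional velocity field
#'
#' Container for a gridded 4D-flow velocity dataset: three velocity
#' components sampled on a common `(x, y, z, frame)` grid, plus the
#' spatial and temporal metadata needed downstream. Components are stored
#' in grid-axis direction; the anatomical apex-to-base sign convention is
#' applied analytically at computation time (see [cine_mask()]), never by
#' mutating the stored arrays.
#'
#' @param vx,vy,vz 4-D numeric arrays `(x, y, z, frame)` of velocity in
#'   cm/s along the three grid axes. All three must share one shape.
#' @param spacing Numeric length-3, voxel size in mm per spatial axis
#'   (all entries > 0).
#' @param rr_interval Cardiac cycle duration in seconds.
#' @param venc Optional velocity-encoding limit in cm/s; speeds beyond it
#'   would have aliased at acquisition. Stored for quality reporting only
#'   (see [venc_quality()]); values above `venc` are permitted.
#' @param magnitude Optional 4-D array of signal magnitude (arbitrary
#'   units) on the same grid, used by [estimate_static_mask()] to restrict
#'   the static-tissue search to the body.
#'
#' @return An object of class `velocity_field`: a list with elements
#'   `vx`, `vy`, `vz`, `magnitude`, `spacing`, `n_frames`, `rr_interval`,
#'   `venc`.
#' @seealso [cine_mask()], [read_velocity_series()], [venc_quality()]
#' @export
#' @examples
#' dims <- c(8, 8, 6, 4)
#' vf <- velocity_field(array(0, dims), array(0, dims), array(1, dims),
#'                      spacing = c(2, 2, 2), rr_interval = 1)
#' vf
velocity_field <- function(vx, vy, vz, spacing, rr_interval,
                           venc = NULL, magnitude = NULL) {
  vx <- as_array4d(vx, "vx"); vy <- as_array4d(vy, "vy"); vz <- as_array4d(vz, "vz")
  if (!identical(dim(vx), dim(vy)) || !identical(dim(vx), dim(vz))) {
    stop("velocity components must share one shape; got ",
         paste(dim(vx), collapse = "x"), " / ",
         paste(dim(vy), collapse = "x"), " / ",
         paste(dim(vz), collapse = "x"), call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  }
  n_frames <- dim(vx)[4]
  if (n_frames < 2) stop("a velocity field needs at least 2 cardiac frames", call. = FALSE)
  rr_interval <- as.numeric(rr_interval)
  if (!is.finite(rr_interval) || rr_interval <= 0) {
    stop("`rr_interval` must be a positive duration in seconds", call. = FALSE)
  }
  if (!is.null(magnitude)) {
    magnitude <- as_array4d(magnitude, "magnitude")
    if (!identical(dim(magnitude), dim(vx))) {
      stop("`magnitude` must share the velocity grid", call. = FALSE)
    }
  }
  structure(
    list(vx = vx, vy = vy, vz = vz, magnitude = magnitude,
         spacing = spacing, n_frames = n_frames,
         rr_interval = rr_interval, venc = venc),
    class = "velocity_field"
  )
}

as_array4d <- function(a, name) {
  a <- unclass(a)
  attributes(a) <- attributes(a)["dim"]
  if (is.null(dim(a)) || length(dim(a)) != 4) {
    stop("`", name, "` must be a 4-D array (x, y, z, frame)", call. = FALSE)
  }
  storage.mode(a) <- "double"
  a
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- dim(x$vx)
  cat("<velocity_field> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " frames\n", sep = "")
  cat("  spacing: ", paste(format(x$spacing), collapse = " x "),
      " mm; RR ", format(x$rr_interval), " s", sep = "")
  if (!is.null(x$venc)) cat("; VENC ", format(x$venc), " cm/s", sep = "")
  cat("\n  peak speed: ", format(max(speed_of(x)), digits = 4), " cm/s\n", sep = "")
  invisible(x)
}

speed_of <- function(field) {
  sqrt(field$vx^2 + field$vy^2 + field$vz^2)
}

#' Flag velocities beyond the velocity-encoding limit
#'
#' Speeds exceeding the VENC are physically possible in the reconstruction
#' only as aliasing artefacts; they are not removed, but reported so a
#' dataset can be screened before analysis.
#'
#' @param field A [velocity_field()] with a non-`NULL` `venc`.
#' @return A tibble with one row per cardiac frame: the number and
#'   fraction of voxels whose speed exceeds the VENC.
#' @export
venc_quality <- function(field) {
  stopifnot(inherits(field, "velocity_field"))
  if (is.null(field$venc)) {
    stop("field carries no `venc`; nothing to flag", call. = FALSE)
  }
  sp <- speed_of(field)
  n_vox <- prod(dim(sp)[1:3])
  over <- apply(sp > field$venc, 4, sum)
  tibble::tibble(
    frame = seq_len(field$n_frames),
    n_over_venc = as.integer(over),
    frac_over_venc = over / n_vox
  )
}

#' Frame sampling times of a velocity field
#'
#' Frames sample the cardiac cycle uniformly; frame `k` is at
#' `(k - 1) / n_frames * rr_interval` seconds after the cycle origin.
#'
#' @param field A [velocity_field()].
#' @return Numeric vector of length `n_frames`, in seconds.
#' @keywords internal
frame_times <- function(field) {
  (seq_len(field$n_frames) - 1) * field$rr_interval / field$n_frames
}
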