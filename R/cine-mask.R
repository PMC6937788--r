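#' Time-resolved binary LV-cavity segmentation
#'
#' A per-frame binary mask of the left-ventricular blood pool on the same
#' grid as the velocity data, together with the orientation metadata that
#' fixes the anatomical sign convention: which grid axis is the short-axis
#' stack direction, and which way along it points from apex to base.
#' Positive through-plane flow is defined as apex-to-base.
#'
#' @param mask 4-D logical (or 0/1 numeric) array `(x, y, z, frame)`.
#'   Every frame must contain at least one in-mask voxel.
#' @param slice_axis Which spatial axis (1, 2 or 3) is the short-axis
#'   stack direction.
#' @param apex_to_base_sign `+1` if increasing index along `slice_axis`
#'   runs apex to base, `-1` otherwise.
#' @param spacing Numeric length-3 voxel size in mm (same convention as
#'   [velocity_field()]).
#'
#' @return An object of class `cine_mask`.
#' @export
cine_mask <- function(mask, slice_axis = 3L, apex_to_base_sign = 1L,
                      spacing = c(1, 1, 1)) {
  m <- unclass(mask)
  attributes(m) <- attributes(m)["dim"]
  if (is.null(dim(m)) || length(dim(m)) != 4) {
    stop("`mask` must be a 4-D array (x, y, z, frame)", call. = FALSE)
  }
  vals <- unique(as.vector(m))
  if (!all(vals %in% c(0, 1, TRUE, FALSE))) {
    stop("mask contains non-binary values (found ",
         paste(utils::head(setdiff(vals, c(0, 1)), 3), collapse = ", "),
         "); expected {0, 1}", call. = FALSE)
  }
  storage.mode(m) <- "logical"
  per_frame <- apply(m, 4, any)
  if (!all(per_frame)) {
    stop("mask is empty at frame(s) ",
         paste(which(!per_frame), collapse = ", "), call. = FALSE)
  }
  slice_axis <- as.integer(slice_axis)
  if (!slice_axis %in% 1:3) stop("`slice_axis` must be 1, 2 or 3", call. = FALSE)
  apex_to_base_sign <- as.integer(sign(apex_to_base_sign))
  if (!apex_to_base_sign %in% c(-1L, 1L)) {
    stop("`apex_to_base_sign` must be +1 or -1", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3 || any(spacing <= 0)) {
    stop("`spacing` must be 3 positive voxel sizes in mm", call. = FALSE)
  }
  structure(
    list(mask = m, slice_axis = slice_axis,
         apex_to_base_sign = apex_to_base_sign, spacing = spacing),
    class = "cine_mask"
  )
}

#' @export
print.cine_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat("<cine_mask> ", paste(d[1:3], collapse = " x "), " voxels, ",
      d[4], " frames; slice axis ", x$slice_axis,
      " (apex→base sign ", ifelse(x$apex_to_base_sign > 0, "+1", "-1"),
      ")\n", sep = "")
  vol <- apply(x$mask, 4, sum) * prod(x$spacing) / 1000
  cat("  cavity volume: ", format(min(vol), digits = 4), " - ",
      format(max(vol), digits = 4), " mL\n", sep = "")
  invisible(x)
}

check_same_grid <- function(field, seg) {
  if (!identical(dim(field$vx)[1:3], dim(seg$mask)[1:3]) ||
      dim(field$vx)[4] != dim(seg$mask)[4]) {
    stop("mask grid ", paste(dim(seg$mask), collapse = "x"),
         " does not match velocity grid ", paste(dim(field$vx), collapse = "x"),
         "; inputs must be co-registered upstream, they are never resampled here",
         call. = FALSE)
  }
  if (!isTRUE(all.equal(field$spacing, seg$spacing))) {
    stop("mask spacing differs from velocity spacing; refusing to resample",
         call. = FALSE)
  }
  invisible(TRUE)
}

# component of `field` along the short-axis stack direction, signed so that
# positive = apex->base
throughplane_component <- function(field, seg) {
  comp <- switch(seg$slice_axis, field$vx, field$vy, field$vz)
  comp * seg$apex_to_base_sign
}
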