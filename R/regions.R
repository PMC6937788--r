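#' Partition the short-axis stack into base, mid-ventricle and apex
#'
#' The LV long-axis extent is taken at end diastole as the span from the
#' center of the apical-most in-mask slice to the center of the basal-most
#' in-mask slice, and divided into three equal-length physical thirds.
#' Each slice is labelled by its center coordinate; the apical and
#' mid-ventricular intervals are closed at the apical end and open at the
#' basal end, the basal interval is closed at both ends. Slices outside
#' the extent are labelled `outside`.
#'
#' @param seg A [cine_mask()].
#' @param ed_frame End-diastolic frame used to find the extent; default
#'   the frame of maximum cavity volume.
#' @return A tibble of class `region_partition` with columns `slice`,
#'   `z_mm` (grid coordinate along the stack), `dist_apex_mm` and
#'   `region` (factor `apex`/`mid`/`base`/`outside`). Third boundaries in
#'   mm from the apex are attached as attribute `boundaries_mm`.
#' @export
partition_regions <- function(seg, ed_frame = NULL) {
  stopifnot(inherits(seg, "cine_mask"))
  ax <- seg$slice_axis
  sp <- seg$spacing[ax]
  if (is.null(ed_frame)) {
    ed_frame <- which.max(apply(seg$mask, 4, sum))
  }
  ed_mask <- index_frame(seg$mask, ed_frame)
  n_slices <- dim(seg$mask)[ax]
  in_slice <- vapply(seq_len(n_slices), function(k) {
    any(index_slice(ed_mask, ax, k))
  }, logical(1))
  if (sum(in_slice) < 3) {
    stop("need at least 3 in-mask slices at end diastole to form three ",
         "regions; got ", sum(in_slice), call. = FALSE)
  }
  idx <- which(in_slice)
  apex_slice <- if (seg$apex_to_base_sign > 0) min(idx) else max(idx)
  base_slice <- if (seg$apex_to_base_sign > 0) max(idx) else min(idx)
  z_mm <- (seq_len(n_slices) - 1) * sp
  dist <- (seq_len(n_slices) - apex_slice) * sp * seg$apex_to_base_sign
  lz <- (base_slice - apex_slice) * sp * seg$apex_to_base_sign
  b <- c(0, lz / 3, 2 * lz / 3, lz)
  region <- rep("outside", n_slices)
  inside <- dist >= 0 & dist <= lz
  region[inside & dist < b[2]] <- "apex"
  region[inside & dist >= b[2] & dist < b[3]] <- "mid"
  region[inside & dist >= b[3]] <- "base"
  out <- tibble::tibble(
    slice = seq_len(n_slices), z_mm = z_mm, dist_apex_mm = dist,
    region = factor(region, levels = c("apex", "mid", "base", "outside")))
  structure(out, class = c("region_partition", class(out)),
            boundaries_mm = b, ed_frame = ed_frame,
            slice_axis = ax, apex_to_base_sign = seg$apex_to_base_sign,
            apex_slice = apex_slice, base_slice = base_slice,
            slice_spacing = sp)
}

# frame t of a 4-D array
index_frame <- function(a, t) {
  d <- dim(a)
  array(a[(t - 1) * prod(d[1:3]) + seq_len(prod(d[1:3]))], d[1:3])
}

# slice k along axis ax of a 3-D array
index_slice <- function(a, ax, k) {
  switch(ax, a[k, , ], a[, k, ], a[, , k])
}

# vector mapping linear voxel index (3-D) -> slice index along axis
slice_index_vector <- function(dims, ax) {
  as.vector(slice.index(array(0L, dims), ax))
}
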