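#' Per-slice and regional through-plane flow curves
#'
#' For every labelled short-axis slice and cardiac frame, through-plane
#' flow is the mean signed through-plane velocity over in-mask voxels
#' (cm/s) times the luminal cross-sectional area (in-mask voxel count
#' times in-plane voxel area, cm^2), converted to L/min. The mask at the
#' same frame defines the lumen, so the area is time-varying. The
#' regional curve is the arithmetic mean of its member slices' curves;
#' a slice that is empty at some frame is skipped at that frame (and
#' counted in the `n_skipped` attribute). Positive flow is apex to base,
#' so peak positive flow is systolic ejection.
#'
#' @param field A [velocity_field()].
#' @param seg A [cine_mask()] on the same grid.
#' @param partition A [partition_regions()] result; computed from `seg`
#'   when omitted.
#' @return An object of class `flow_curves`: list of two tibbles,
#'   `slices` (`slice`, `region`, `frame`, `time_s`, `flow_lpm`) and
#'   `regions` (`region`, `frame`, `time_s`, `flow_lpm`).
#' @export
throughplane_flow <- function(field, seg, partition = NULL) {
  stopifnot(inherits(field, "velocity_field"), inherits(seg, "cine_mask"))
  check_same_grid(field, seg)
  if (is.null(partition)) partition <- partition_regions(seg)
  ax <- seg$slice_axis
  dims <- dim(field$vx)[1:3]
  nt <- field$n_frames
  comp <- throughplane_component(field, seg)          # + = apex->base, cm/s
  area_vox <- prod(seg$spacing[-ax]) / 100            # cm^2 per voxel
  siv <- slice_index_vector(dims, ax)
  keep <- which(partition$region != "outside")
  nvox3 <- prod(dims)

  flow <- matrix(NA_real_, length(keep), nt,
                 dimnames = list(slice = keep, frame = seq_len(nt)))
  for (t in seq_len(nt)) {
    sel <- (t - 1) * nvox3 + seq_len(nvox3)
    msk <- as.vector(seg$mask)[sel]
    v <- as.vector(comp)[sel][msk]
    s <- siv[msk]
    sums <- rowsum(v, s)                              # per occupied slice
    occ <- as.integer(rownames(sums))
    hit <- match(keep, occ)
    flow[, t] <- ifelse(is.na(hit), NA_real_, sums[hit] * area_vox * 0.06)
  }
  n_skipped <- sum(is.na(flow))
  if (n_skipped > 0) {
    message("throughplane_flow: ", n_skipped,
            " slice-frame(s) had an empty mask and were skipped")
  }
  tt <- frame_times(field)
  slices <- tibble::tibble(
    slice = rep(keep, nt),
    region = rep(partition$region[keep], nt),
    frame = rep(seq_len(nt), each = length(keep)),
    time_s = rep(tt, each = length(keep)),
    flow_lpm = as.vector(flow))
  regions <- slices |>
    dplyr::group_by(.data$region, .data$frame, .data$time_s) |>
    dplyr::summarise(flow_lpm = mean(.data$flow_lpm, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(flow_lpm = ifelse(is.nan(.data$flow_lpm), NA_real_,
                                    .data$flow_lpm)) |>
    dplyr::arrange(.data$region, .data$frame)
  structure(list(slices = slices, regions = regions),
            class = "flow_curves", n_skipped = n_skipped,
            partition = partition)
}

#' @export
print.flow_curves <- function(x, ...) {
  nt <- max(x$regions$frame)
  cat("<flow_curves> ", dplyr::n_distinct(x$slices$slice), " slices, ",
      nt, " frames\n", sep = "")
  pk <- peak_flows(x)
  print(pk)
  invisible(x)
}

#' Peak systolic and diastolic regional flow
#'
#' Peak systolic flow is the maximum of the regional flow curve (positive
#' = apex to base = ejection); peak diastolic flow is the magnitude of
#' the minimum. Both are attained values of the curve; ties are broken by
#' the earliest frame.
#'
#' @param curves A `flow_curves` object from [throughplane_flow()], or a
#'   tibble with columns `region`, `frame`, `flow_lpm`.
#' @return Tibble with one row per region: `peak_systolic`,
#'   `frame_systolic`, `peak_diastolic` (magnitude), `frame_diastolic`.
#' @export
peak_flows <- function(curves) {
  reg <- if (inherits(curves, "flow_curves")) curves$regions else curves
  stopifnot(all(c("region", "frame", "flow_lpm") %in% names(reg)))
  reg |>
    dplyr::group_by(.data$region) |>
    dplyr::group_modify(function(d, key) {
      v <- d$flow_lpm
      if (all(is.na(v))) {
        stop("flow curve for region '", key$region,
             "' is all-NA; cannot locate peaks", call. = FALSE)
      }
      i_max <- which(v == max(v, na.rm = TRUE))[1]   # earliest tie wins
      i_min <- which(v == min(v, na.rm = TRUE))[1]
      tibble::tibble(peak_systolic = v[i_max],
                     frame_systolic = d$frame[i_max],
                     peak_diastolic = abs(v[i_min]),
                     frame_diastolic = d$frame[i_min])
    }) |>
    dplyr::ungroup()
}

#' Flow curves as a wide CSV-ready table
#' @param curves A `flow_curves` object.
#' @param level `"slices"` or `"regions"`.
#' @return Wide tibble, one row per slice/region, one column per frame.
#' @export
flow_curve_table <- function(curves, level = c("regions", "slices")) {
  level <- match.arg(level)
  curves[[level]] |>
    dplyr::select(-"time_s") |>
    tidyr::pivot_wider(names_from = "frame", values_from = "flow_lpm",
                       names_prefix = "frame_")
}
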