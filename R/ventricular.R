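#' Cavity volumes and global function from the cine segmentation
#'
#' Volume at each frame is the in-mask voxel count times the voxel volume
#' (Simpson-style voxel counting; no surface fitting). End diastole and
#' end systole are the frames of maximum and minimum volume (earliest
#' frame on ties), from which EDV, ESV, stroke volume and ejection
#' fraction follow. Whether papillary muscles or the outflow tract are
#' included is a property of the input segmentation, not of this
#' computation.
#'
#' @param seg A [cine_mask()]; every frame must be nonempty.
#' @param heart_rate Optional heart rate in bpm; adds cardiac output.
#' @return Object of class `ventricular_function`: list with `volume`
#'   (tibble `frame`, `volume_ml`), `edv_ml`, `esv_ml`, `sv_ml`, `ef_pct`,
#'   `co_l_min` (or `NA`), `ed_frame`, `es_frame`.
#' @export
cavity_volumes <- function(seg, heart_rate = NULL) {
  stopifnot(inherits(seg, "cine_mask"))
  v_vox_ml <- prod(seg$spacing) / 1000
  counts <- apply(seg$mask, 4, sum)
  if (any(counts == 0)) {
    stop("mask empty at frame(s) ", paste(which(counts == 0), collapse = ", "),
         call. = FALSE)
  }
  vol <- counts * v_vox_ml
  ed <- which.max(vol); es <- which.min(vol)    # earliest frame on ties
  edv <- vol[ed]; esv <- vol[es]
  sv <- edv - esv
  structure(list(
    volume = tibble::tibble(frame = seq_along(vol), volume_ml = vol),
    edv_ml = edv, esv_ml = esv, sv_ml = sv, ef_pct = 100 * sv / edv,
    co_l_min = if (is.null(heart_rate)) NA_real_ else cardiac_output(sv, heart_rate),
    heart_rate = heart_rate %||% NA_real_,
    ed_frame = as.integer(ed), es_frame = as.integer(es)
  ), class = "ventricular_function")
}

#' @export
print.ventricular_function <- function(x, ...) {
  cat("<ventricular_function> EDV ", format(x$edv_ml, digits = 4),
      " mL, ESV ", format(x$esv_ml, digits = 4), " mL, SV ",
      format(x$sv_ml, digits = 4), " mL, EF ",
      format(x$ef_pct, digits = 3), "%\n", sep = "")
  cat("  ED frame ", x$ed_frame, ", ES frame ", x$es_frame, sep = "")
  if (is.finite(x$co_l_min)) {
    cat(", CO ", format(x$co_l_min, digits = 3), " L/min", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @importFrom generics glance
#' @method glance ventricular_function
#' @export
glance.ventricular_function <- function(x, ...) {
  tibble::tibble(edv_ml = x$edv_ml, esv_ml = x$esv_ml, sv_ml = x$sv_ml,
                 ef_pct = x$ef_pct, co_l_min = x$co_l_min,
                 ed_frame = x$ed_frame, es_frame = x$es_frame)
}

#' Cardiac output from stroke volume and heart rate
#' @param sv Stroke volume, mL (>= 0).
#' @param hr Heart rate, bpm (> 0).
#' @return Cardiac output in L/min.
#' @export
#' @examples
#' cardiac_output(95, 60)   # 5.7 L/min
cardiac_output <- function(sv, hr) {
  stopifnot(all(sv >= 0), all(hr > 0))
  sv * hr / 1000
}

#' Infarct size from 17-segment transmurality scores
#'
#' Each AHA segment is scored 0-4 for infarct transmurality (0 = none,
#' 4 = > 75% transmural); infarct size is the mean score divided by four,
#' expressed as a percentage of the myocardium.
#'
#' @param scores Integer vector of exactly 17 scores in `{0, ..., 4}`.
#' @return Infarct fraction in percent, in `[0, 100]`.
#' @export
#' @examples
#' infarct_fraction(rep(4, 17))   # 100
infarct_fraction <- function(scores) {
  scores <- as.vector(scores)
  if (length(scores) != 17) {
    stop("expected exactly 17 segment scores, got ", length(scores),
         call. = FALSE)
  }
  if (any(is.na(scores)) || any(scores != round(scores)) ||
      any(scores < 0 | scores > 4)) {
    stop("segment scores must be integers in {0, 1, 2, 3, 4}", call. = FALSE)
  }
  mean(scores) / 4 * 100
}
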