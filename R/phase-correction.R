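#' @name phase_correction
#' @title Background phase-error correction
#'
#' @description
#' Phase-contrast velocity data carries a smooth, time-constant spatial
#' offset (residual eddy-current / background phase error). Following
#' standard PC-MRI practice, the offset is modelled per velocity component
#' as a 3rd-order 3-D polynomial fitted to the velocity of static tissue
#' and subtracted everywhere. The basis is the 20 monomials
#' `x^a y^b z^c` with `a + b + c <= 3`, evaluated in coordinates
#' normalized to `[-1, 1]` over the grid extent for conditioning.
NULL

# exponent table of the 20-term cubic basis, fixed column order
cubic_exponents <- function() {
  ex <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  ex <- ex[ex$a + ex$b + ex$c <= 3, ]
  ex <- ex[order(ex$a + ex$b + ex$c, ex$a, ex$b, ex$c), ]
  rownames(ex) <- NULL
  ex
}

# normalized voxel-center coordinates in [-1, 1] per axis
normalized_coords <- function(dims) {
  lapply(1:3, function(ax) {
    n <- dims[ax]
    if (n == 1) return(0)
    2 * (seq_len(n) - 1) / (n - 1) - 1
  })
}

# design matrix of the cubic basis at the given voxels (linear indices into
# the 3-D grid); returns n_vox x 20
cubic_design <- function(dims, voxels = NULL) {
  co <- normalized_coords(dims)
  idx <- if (is.null(voxels)) seq_len(prod(dims)) else voxels
  sub <- arrayInd(idx, dims)
  x <- co[[1]][sub[, 1]]; y <- co[[2]][sub[, 2]]; z <- co[[3]][sub[, 3]]
  ex <- cubic_exponents()
  B <- matrix(0, length(idx), nrow(ex))
  for (j in seq_len(nrow(ex))) {
    B[, j] <- x^ex$a[j] * y^ex$b[j] * z^ex$c[j]
  }
  colnames(B) <- paste0("x", ex$a, "y", ex$b, "z", ex$c)
  B
}

#' Estimate a static-tissue mask from temporal velocity variation
#'
#' A voxel is called static when the temporal standard deviation of its
#' speed lies below a percentile of all in-body voxels. The percentile
#' rule is this package's convention (the criterion is not standardised);
#' phantom validation uses known-truth static regions instead. The body
#' is defined by a magnitude threshold when the field carries a magnitude
#' image, otherwise all voxels are candidates.
#'
#' @param field A [velocity_field()] with at least 2 frames.
#' @param sd_percentile Percentile (0-100) of the temporal-SD
#'   distribution below which a voxel counts as static. Default 30.
#' @param magnitude_quantile When a magnitude image is present, voxels
#'   with magnitude above this quantile (default 0.25) of the temporal
#'   mean magnitude form the body.
#' @return 3-D logical array; `TRUE` = static.
#' @export
estimate_static_mask <- function(field, sd_percentile = 30,
                                 magnitude_quantile = 0.25) {
  stopifnot(inherits(field, "velocity_field"))
  sp <- speed_of(field)
  nt <- field$n_frames
  mu <- apply(sp, 1:3, mean)
  sd3 <- sqrt(pmax(apply(sp^2, 1:3, mean) - mu^2, 0) * nt / (nt - 1))
  body <- if (!is.null(field$magnitude)) {
    mg <- apply(field$magnitude, 1:3, mean)
    mg > stats::quantile(mg, magnitude_quantile)
  } else {
    array(TRUE, dim(sd3))
  }
  thr <- stats::quantile(sd3[body], sd_percentile / 100, names = FALSE)
  static <- body & (sd3 <= thr)
  if (!any(static)) {
    stop("static-tissue mask is empty; increase `sd_percentile`", call. = FALSE)
  }
  static
}

#' Fit the 3rd-order background phase polynomial over static tissue
#'
#' Least-squares fit, per velocity component, of the temporal-mean
#' velocity at static-tissue voxels to the 20-term cubic basis. The
#' background error is modelled as time-constant, so the temporal mean is
#' the fit target.
#'
#' @param field A [velocity_field()].
#' @param static_mask 3-D logical array marking static voxels (at least
#'   20, with non-degenerate spatial spread).
#' @return An object of class `poly_coeffs`: a 20 x 3 coefficient matrix
#'   (basis term x component) with the exponent table attached.
#' @export
fit_background_phase <- function(field, static_mask) {
  stopifnot(inherits(field, "velocity_field"))
  dims <- dim(field$vx)[1:3]
  if (!identical(dim(static_mask), dims)) {
    stop("`static_mask` must match the spatial grid", call. = FALSE)
  }
  vox <- which(static_mask)
  if (length(vox) < 20) {
    stop("need >= 20 static voxels to fit 20 coefficients; got ",
         length(vox), call. = FALSE)
  }
  B <- cubic_design(dims, vox)
  qrB <- qr(B)
  if (qrB$rank < ncol(B)) {
    stop("static-voxel design is rank-deficient (rank ", qrB$rank,
         "/", ncol(B), ", condition number ", format(kappa(B), digits = 3),
         "); static tissue lacks spatial spread", call. = FALSE)
  }
  target <- vapply(c("vx", "vy", "vz"), function(cmp) {
    tm <- rowMeans(matrix(field[[cmp]], ncol = field$n_frames))
    tm[vox]
  }, numeric(length(vox)))
  coef <- qr.coef(qrB, target)
  structure(coef, class = "poly_coeffs", exponents = cubic_exponents(),
            dims = dims)
}

#' @export
print.poly_coeffs <- function(x, ...) {
  cat("<poly_coeffs> 3rd-order background-phase polynomial, 20 terms x 3 components\n")
  cat("  max |coefficient| per component (cm/s):",
      paste(format(apply(abs(unclass(x)), 2, max), digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

#' Evaluate a fitted background-phase polynomial on the full grid
#' @param coeffs A `poly_coeffs` object.
#' @param dims Spatial grid dimensions.
#' @return List of three 3-D arrays (one offset field per component).
#' @keywords internal
evaluate_background_phase <- function(coeffs, dims) {
  B <- cubic_design(dims)
  off <- B %*% unclass(coeffs)
  lapply(1:3, function(j) array(off[, j], dims))
}

#' Subtract the fitted background phase from every frame
#'
#' The evaluated polynomial (time-constant) is subtracted from each frame
#' of each component. Temporal fluctuations `v(t) - mean_t(v)` are
#' preserved voxel-wise exactly.
#'
#' @param field A [velocity_field()].
#' @param coeffs A `poly_coeffs` from [fit_background_phase()].
#' @return The corrected [velocity_field()].
#' @export
correct_background_phase <- function(field, coeffs) {
  stopifnot(inherits(field, "velocity_field"), inherits(coeffs, "poly_coeffs"))
  dims <- dim(field$vx)[1:3]
  off <- evaluate_background_phase(coeffs, dims)
  nt <- field$n_frames
  for (j in 1:3) {
    cmp <- c("vx", "vy", "vz")[j]
    field[[cmp]] <- field[[cmp]] - as.vector(off[[j]])  # recycles over frames
  }
  field
}

#' Serialize fitted correction coefficients for audit
#' @param coeffs A `poly_coeffs`.
#' @param path JSON output path.
#' @return The path, invisibly.
#' @export
write_poly_coeffs <- function(coeffs, path) {
  ex <- attr(coeffs, "exponents")
  jsonlite::write_json(
    list(exponents = ex, coefficients = unclass(coeffs)),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}
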