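#' Plug-flow cylinder phantom with analytic compartment fractions
#'
#' A static cylindrical cavity (apex closed end at long-axis position 0,
#' open base at `length`) carrying spatially uniform axial plug flow:
#' inflow (base to apex, negative through-plane sign) during the diastolic
#' half of the cycle with total axial displacement `d_in`, outflow during
#' the systolic half with displacement `d_out`. Because transport is pure
#' 1-D translation, the four flow compartments have closed-form fractions
#' from interval overlaps along the axis: blood in the top `d_in` of the
#' cavity at end diastole entered during diastole, blood in the top
#' `d_out` leaves during systole, so e.g. direct flow =
#' `min(d_in, d_out) / length`.
#'
#' The velocity-versus-phase waveform is trapezoidal: samples are zero at
#' the ED and ES transition frames and constant in between, so the
#' linearly phase-interpolated field integrates exactly to the configured
#' displacements. Velocity is defined over the whole grid (plug flow in a
#' pipe), so trajectories that exit the cavity keep moving; the cycle
#' starts at end diastole (frame 1), with systole in the first half.
#'
#' @param radius Cylinder radius, cm.
#' @param length Cylinder length along the long axis, cm.
#' @param d_in Diastolic inflow displacement, cm, in `[0, length]`.
#' @param d_out Systolic outflow displacement, cm, in `[0, length]`.
#' @param n_frames Even number of cardiac frames (>= 4).
#' @param rr_interval Cycle duration, s.
#' @param spacing Isotropic voxel size, mm.
#' @param margin Grid margin, voxels.
#' @return A list `field`, `seg`, `truth` as in [ellipsoid_phantom()];
#'   `truth$fractions` holds the analytic compartment percentages
#'   (`direct`, `retained`, `delayed`, `residual`, summing to 100) and
#'   `truth$excluded_pct` the expected wall-crossing exclusion (0: all
#'   transit is through the basal end plane).
#' @export
plug_phantom <- function(radius = 1.5, length = 8, d_in = 4, d_out = 4,
                         n_frames = 40, rr_interval = 1, spacing = 2.5,
                         margin = 3) {
  stopifnot(radius > 0, length > 0, n_frames >= 4, n_frames %% 2 == 0)
  if (d_in < 0 || d_in > length || d_out < 0 || d_out > length) {
    stop("displacements must lie in [0, length]: d_in = ", d_in,
         ", d_out = ", d_out, ", length = ", length, call. = FALSE)
  }
  sp <- spacing
  r_mm <- radius * 10; L_mm <- length * 10
  head_mm <- max(d_in, d_out) * 10 + margin * sp
  nxy <- 2L * ceiling(r_mm / sp) + 2L * margin
  nz <- as.integer(ceiling((L_mm + head_mm) / sp) + margin)
  dims <- c(nxy, nxy, nz)
  z0_mm <- (margin - 0.5) * sp
  cx <- (dims[1] - 1) / 2 * sp; cy <- (dims[2] - 1) / 2 * sp

  Tc <- rr_interval; dt <- Tc / n_frames
  half <- n_frames / 2
  # plateau amplitudes making the interpolated waveform integrate exactly
  v_sys <- if (d_out > 0) d_out / (Tc / 2 - dt) else 0   # cm/s, apex->base
  v_dia <- if (d_in > 0) d_in / (Tc / 2 - dt) else 0
  v_t <- numeric(n_frames)
  if (half >= 2) v_t[2:half] <- v_sys          # frames strictly inside systole
  if (half + 2 <= n_frames) v_t[(half + 2):n_frames] <- -v_dia
  # frames 1 (ED) and half+1 (ES) stay zero

  xc <- (seq_len(dims[1]) - 1) * sp - cx
  yc <- (seq_len(dims[2]) - 1) * sp - cy
  zc <- (seq_len(dims[3]) - 1) * sp - z0_mm
  in_r <- outer(xc^2, yc^2, `+`) < r_mm^2
  in_z <- zc >= 0 & zc <= L_mm
  mask3 <- array(outer(in_r, in_z, `&`), dims)
  d4 <- c(dims, n_frames)
  mask <- array(mask3, d4)
  vz <- array(rep(v_t, each = prod(dims)), d4)
  zero <- array(0, d4)

  mn <- min(d_in, d_out)
  fr <- c(direct = mn, retained = d_in - mn, delayed = d_out - mn,
          residual = length - max(d_in, d_out)) / length * 100
  truth <- structure(list(
    fractions = as.list(fr), excluded_pct = 0,
    volume = tibble::tibble(frame = seq_len(n_frames),
                            time_s = (seq_len(n_frames) - 1) * dt,
                            volume_ml = pi * radius^2 * length),
    ed_frame = 1L, es_frame = as.integer(half + 1),
    edv_ml = pi * radius^2 * length, esv_ml = pi * radius^2 * length,
    apex_mm = z0_mm, base_mm = z0_mm + L_mm,
    phase_coeffs = NULL,
    params = list(radius = radius, length = length, d_in = d_in,
                  d_out = d_out, n_frames = n_frames,
                  rr_interval = rr_interval, spacing = sp, dims = dims)
  ), class = "phantom_truth")

  field <- velocity_field(zero, zero, vz, spacing = rep(sp, 3),
                          rr_interval = rr_interval)
  seg <- cine_mask(mask, slice_axis = 3L, apex_to_base_sign = 1L,
                   spacing = rep(sp, 3))
  list(field = field, seg = seg, truth = truth)
}

#' Add a planted background-phase offset to a velocity field
#'
#' Adds a time-constant 3rd-order polynomial offset (the model class of
#' [fit_background_phase()]) to every frame of each component, emulating
#' residual eddy-current phase error. Used with the phantoms to give the
#' correction stage a known truth.
#'
#' @param field A [velocity_field()].
#' @param coeffs 20 x 3 numeric matrix of coefficients (basis term x
#'   component) in the [cubic_exponents()] order, or a `poly_coeffs`.
#' @return The field with the offset added; the planted coefficients are
#'   attached as attribute `"planted_coeffs"`.
#' @export
plant_background_phase <- function(field, coeffs) {
  stopifnot(inherits(field, "velocity_field"))
  coeffs <- as_poly_coeffs(coeffs)
  dims <- dim(field$vx)[1:3]
  off <- evaluate_background_phase(coeffs, dims)
  for (j in 1:3) {
    cmp <- c("vx", "vy", "vz")[j]
    field[[cmp]] <- field[[cmp]] + as.vector(off[[j]])
  }
  attr(field, "planted_coeffs") <- coeffs
  field
}

#' Coerce a plain coefficient matrix to `poly_coeffs`
#' @param x 20 x 3 numeric matrix, or an existing `poly_coeffs`.
#' @return A `poly_coeffs` object.
#' @export
as_poly_coeffs <- function(x) {
  if (inherits(x, "poly_coeffs")) return(x)
  x <- as.matrix(x)
  if (nrow(x) != 20 || ncol(x) != 3) {
    stop("background-phase coefficients must be a 20 x 3 matrix ",
         "(cubic basis term x velocity component)", call. = FALSE)
  }
  structure(x, class = "poly_coeffs", exponents = cubic_exponents())
}

#' Add i.i.d. Gaussian velocity noise
#'
#' Zero-mean Gaussian noise of the given SD is added independently to
#' every voxel, frame and component. Reproducible under `seed`.
#'
#' @param field A [velocity_field()].
#' @param sd Noise standard deviation, cm/s (>= 0).
#' @param seed Optional RNG seed.
#' @return The noisy field.
#' @export
add_velocity_noise <- function(field, sd, seed = NULL) {
  stopifnot(inherits(field, "velocity_field"), sd >= 0)
  if (sd == 0) return(field)
  if (!is.null(seed)) set.seed(seed)
  n <- length(field$vx)
  for (cmp in c("vx", "vy", "vz")) {
    field[[cmp]] <- field[[cmp]] + array(stats::rnorm(n, 0, sd), dim(field[[cmp]]))
  }
  field
}
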