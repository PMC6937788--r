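#' Deforming half-ellipsoid LV phantom with closed-form flow truth
#'
#' Generates a synthetic 4D-flow dataset emulating a contracting left
#' ventricle, with analytic ground truth for every downstream quantity.
#' The cavity is a half-ellipsoid: apex closed at long-axis position 0,
#' open base at `L`, wall radius
#' `r_w(z, t) = R(t) * sqrt(1 - ((L - z)/L)^2)` with
#' `R(t) = R0 * (1 - alpha * sin(pi t / T)^2)`. The first half of the
#' cycle is systolic (radius decreasing), the second diastolic; end
#' diastole is the frame of maximum cavity volume (frame 1).
#'
#' Velocities follow from incompressibility in closed form: the axial
#' velocity is uniform over each cross-section with
#' `v_z * A = -d/dt V_apical(z, t)` (flux positive apex to base), and the
#' radial velocity `v_r = (r / r_w) * dr_w/dt` reduces to the affine field
#' `v_x = (x - cx) * R'(t)/R(t)`. Velocity is zero outside the cavity
#' (static tissue). The analytic per-slice flux and volume curves, ED/ES
#' frames, and cavity geometry are returned as the phantom truth.
#'
#' @param R0 Basal radius at end diastole, cm.
#' @param L Long-axis length, cm.
#' @param alpha Contraction fraction in `[0, 1)`: the basal radius falls
#'   to `R0 * (1 - alpha)` at end systole. `alpha = 0` gives a static
#'   cavity with zero velocity everywhere.
#' @param n_frames Cardiac frames per cycle (>= 2).
#' @param rr_interval Cycle duration, s.
#' @param spacing Isotropic voxel size, mm.
#' @param dims Optional grid dimensions; by default the grid is sized to
#'   hold the phantom with `margin` voxels on every side.
#' @param margin Margin in voxels used when auto-sizing, and the minimum
#'   accepted clearance when `dims` is given.
#' @param noise_sd Gaussian velocity noise SD in cm/s added to the
#'   returned field (truth always refers to the noiseless field).
#' @param seed RNG seed for the noise.
#'
#' @return A list with elements `field` ([velocity_field()]),
#'   `seg` ([cine_mask()], slice axis 3, apex at low z so
#'   `apex_to_base_sign = +1`) and `truth` (class `phantom_truth`; see
#'   Details).
#'
#' @details `truth` is a list: `slice_flux` (tibble slice x frame of
#'   analytic through-plane flow, L/min, positive apex to base), `volume`
#'   (tibble of analytic cavity volume, mL, per frame), `ed_frame`,
#'   `es_frame`, `edv_ml`, `esv_ml`, `apex_mm`/`base_mm` (long-axis
#'   positions on the grid), and `params` (the configuration).
#' @export
#' @examples
#' ph <- ellipsoid_phantom(R0 = 2, L = 8, alpha = 0.2, n_frames = 10,
#'                         spacing = 2.5)
#' ph$truth$edv_ml
ellipsoid_phantom <- function(R0 = 2, L = 8, alpha = 0.2, n_frames = 20,
                              rr_interval = 1, spacing = 1.25, dims = NULL,
                              margin = 4, noise_sd = 0, seed = NULL) {
  stopifnot(R0 > 0, L > 0, alpha >= 0, alpha < 1, n_frames >= 2, margin >= 2)
  sp <- spacing
  R0_mm <- R0 * 10; L_mm <- L * 10
  if (is.null(dims)) {
    nxy <- 2L * ceiling(R0_mm / sp) + 2L * margin
    nz <- ceiling(L_mm / sp) + 2L * margin
    dims <- c(nxy, nxy, nz)
  }
  dims <- as.integer(dims)
  # apex placed between voxel centers to avoid a degenerate zero-radius slice
  z0_mm <- (margin - 0.5) * sp
  cx <- (dims[1] - 1) / 2 * sp
  cy <- (dims[2] - 1) / 2 * sp
  if (cx < R0_mm + 2 * sp || cy < R0_mm + 2 * sp ||
      dims[3] * sp - (z0_mm + L_mm) < 2 * sp) {
    stop("phantom does not fit in the grid with >= 2 voxels margin; ",
         "enlarge `dims`", call. = FALSE)
  }

  tt <- (seq_len(n_frames) - 1) * rr_interval / n_frames
  Rt <- R0 * (1 - alpha * sin(pi * tt / rr_interval)^2)
  dRt <- -R0 * alpha * (pi / rr_interval) * sin(2 * pi * tt / rr_interval)

  xc <- ((seq_len(dims[1]) - 1) * sp - cx) / 10   # cm from axis
  yc <- ((seq_len(dims[2]) - 1) * sp - cy) / 10
  zc <- ((seq_len(dims[3]) - 1) * sp - z0_mm) / 10  # cm from apex
  r2_xy <- outer(xc^2, yc^2, `+`)                 # nx x ny, cm^2
  m <- (L - zc) / L
  in_long <- zc >= 0 & zc <= L
  s2 <- ifelse(in_long, pmax(1 - m^2, 0), 0)      # (r_w / R)^2
  g <- L * (2 / 3 - m + m^3 / 3)                  # V_apical / (pi R^2)

  d4 <- c(dims, n_frames)
  vx <- array(0, d4); vy <- array(0, d4); vz <- array(0, d4)
  mask <- array(FALSE, d4)
  nxy <- dims[1] * dims[2]
  vx_plane <- matrix(xc, dims[1], dims[2])        # x offset per voxel, cm
  vy_plane <- matrix(yc, dims[1], dims[2], byrow = TRUE)
  for (ti in seq_len(n_frames)) {
    scale_r <- dRt[ti] / Rt[ti]                   # radial rate, 1/s
    for (k in which(in_long)) {
      rw2 <- Rt[ti]^2 * s2[k]
      if (rw2 <= 0) next
      ins <- r2_xy < rw2
      if (!any(ins)) next
      A <- pi * rw2                               # cm^2
      q <- -2 * pi * Rt[ti] * dRt[ti] * g[k]      # cm^3/s, + = apex->base
      vzk <- if (A > 0) q / A else 0
      off <- (ti - 1) * prod(dims) + (k - 1) * nxy
      idx <- off + which(ins)
      mask[idx] <- TRUE
      vz[idx] <- vzk
      vx[idx] <- vx_plane[ins] * scale_r
      vy[idx] <- vy_plane[ins] * scale_r
    }
  }

  volume <- (2 / 3) * pi * Rt^2 * L               # mL
  ed_frame <- which.max(volume)
  es_frame <- which.min(volume)
  slice_flux <- tidyr::expand_grid(slice = seq_len(dims[3]),
                                   frame = seq_len(n_frames))
  qk <- outer(g * in_long, -2 * pi * Rt * dRt)    # slice x frame, cm^3/s
  slice_flux$flow_lpm <- qk[cbind(slice_flux$slice, slice_flux$frame)] * 0.06

  truth <- structure(list(
    slice_flux = tibble::as_tibble(slice_flux),
    volume = tibble::tibble(frame = seq_len(n_frames), time_s = tt,
                            volume_ml = volume),
    ed_frame = ed_frame, es_frame = es_frame,
    edv_ml = max(volume), esv_ml = min(volume),
    apex_mm = z0_mm, base_mm = z0_mm + L_mm,
    phase_coeffs = NULL,
    params = list(R0 = R0, L = L, alpha = alpha, n_frames = n_frames,
                  rr_interval = rr_interval, spacing = sp, dims = dims,
                  noise_sd = noise_sd, seed = seed)
  ), class = "phantom_truth")

  field <- velocity_field(vx, vy, vz, spacing = rep(sp, 3),
                          rr_interval = rr_interval)
  if (noise_sd > 0) field <- add_velocity_noise(field, noise_sd, seed = seed)
  seg <- cine_mask(mask, slice_axis = 3L, apex_to_base_sign = 1L,
                   spacing = rep(sp, 3))
  list(field = field, seg = seg, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat("<phantom_truth> EDV ", format(x$edv_ml, digits = 4), " mL, ESV ",
      format(x$esv_ml, digits = 4), " mL; ED frame ", x$ed_frame,
      ", ES frame ", x$es_frame, "\n", sep = "")
  if (!is.null(x$fractions)) {
    cat("  compartment truth (%):",
        paste(names(x$fractions), round(unlist(x$fractions), 1),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}
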