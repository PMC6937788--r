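#' Seed pathlines from the end-diastolic blood pool
#'
#' Emits one seed per in-mask voxel center at end diastole, or a regular
#' subsample: with `density < 1`, every `stride`-th voxel along each of
#' the two in-plane axes is kept, `stride = round(1 / sqrt(density))`.
#' Each seed carries the blood volume it represents (voxel volume divided
#' by the in-plane sampling density), so compartment fractions remain
#' volume fractions under subsampling.
#'
#' @param seg A [cine_mask()].
#' @param ed_frame End-diastolic frame; default the frame of maximum
#'   cavity volume.
#' @param density Seeding density in `(0, 1]`; 1 = every voxel, 0.25 =
#'   every other voxel along both in-plane axes.
#' @return Tibble `x_mm`, `y_mm`, `z_mm` (voxel-center positions),
#'   `volume_ml`, `slice`.
#' @export
seed_pathlines <- function(seg, ed_frame = NULL, density = 1) {
  stopifnot(inherits(seg, "cine_mask"), density > 0, density <= 1)
  if (is.null(ed_frame)) ed_frame <- which.max(apply(seg$mask, 4, sum))
  dims <- dim(seg$mask)[1:3]
  ed <- index_frame(seg$mask, ed_frame)
  if (!any(ed)) stop("end-diastolic mask is empty", call. = FALSE)
  idx <- which(ed)
  sub <- arrayInd(idx, dims)
  stride <- max(1L, as.integer(round(1 / sqrt(density))))
  inplane <- setdiff(1:3, seg$slice_axis)
  if (stride > 1L) {
    keep <- (sub[, inplane[1]] - 1L) %% stride == 0L &
      (sub[, inplane[2]] - 1L) %% stride == 0L
    sub <- sub[keep, , drop = FALSE]
  }
  vol <- prod(seg$spacing) / 1000 * stride^2
  tibble::tibble(
    x_mm = (sub[, 1] - 1) * seg$spacing[1],
    y_mm = (sub[, 2] - 1) * seg$spacing[2],
    z_mm = (sub[, 3] - 1) * seg$spacing[3],
    volume_ml = vol,
    slice = sub[, seg$slice_axis])
}

# trilinear + periodic-phase-linear velocity sample.
# pos: N x 3 matrix in mm; t: time in s (any real; wrapped into the cycle).
# Returns N x 3 velocities in cm/s. Positions outside the grid are clamped
# to the boundary (the integrator freezes such trajectories separately).
sample_velocity <- function(field, pos, t) {
  dims <- dim(field$vx)[1:3]
  sp <- field$spacing
  nt <- field$n_frames
  dtf <- field$rr_interval / nt
  phase <- (t / dtf) %% nt
  f0 <- floor(phase)
  wt <- phase - f0
  fA <- (f0 %% nt) + 1
  fB <- ((f0 + 1) %% nt) + 1

  u <- sweep(pos, 2, sp, `/`)                 # 0-based voxel coords
  i0 <- pmin(pmax(floor(u), 0), matrix(rep(dims - 2, each = nrow(u)),
                                       ncol = 3))
  w <- pmin(pmax(u - i0, 0), 1)
  nx <- dims[1]; nxy <- dims[1] * dims[2]; nxyz <- prod(dims)
  base <- 1 + i0[, 1] + nx * i0[, 2] + nxy * i0[, 3]
  offs <- c(0, 1, nx, nx + 1, nxy, nxy + 1, nxy + nx, nxy + nx + 1)
  wx <- w[, 1]; wy <- w[, 2]; wz <- w[, 3]
  cw <- cbind((1 - wx) * (1 - wy) * (1 - wz), wx * (1 - wy) * (1 - wz),
              (1 - wx) * wy * (1 - wz),       wx * wy * (1 - wz),
              (1 - wx) * (1 - wy) * wz,       wx * (1 - wy) * wz,
              (1 - wx) * wy * wz,             wx * wy * wz)
  out <- matrix(0, nrow(pos), 3)
  offA <- nxyz * (fA - 1); offB <- nxyz * (fB - 1)
  for (j in 1:3) {
    arr <- field[[c("vx", "vy", "vz")[j]]]
    vA <- 0; vB <- 0
    for (k in 1:8) {
      idx <- base + offs[k]
      vA <- vA + cw[, k] * arr[idx + offA]
      vB <- vB + cw[, k] * arr[idx + offB]
    }
    out[, j] <- (1 - wt) * vA + wt * vB
  }
  out
}

#' Integrate pathlines through the time-resolved velocity field
#'
#' Classic fixed-step 4th-order Runge-Kutta integration of particle
#' trajectories, with trilinear spatial interpolation and linear
#' interpolation in cardiac phase (periodic wrap) of the velocity field.
#' The step is the frame interval divided by `substeps`; backward tracing
#' is integration with a negated time direction (`t_end < t_start`).
#' A trajectory that leaves the image grid is frozen at its last in-grid
#' position; a trajectory that samples a non-finite velocity is flagged
#' invalid.
#'
#' @param field A [velocity_field()].
#' @param seeds Tibble from [seed_pathlines()], or an `n x 3` matrix of
#'   positions in mm.
#' @param t_start,t_end Integration time span in seconds; times outside
#'   `[0, rr_interval)` wrap periodically.
#' @param substeps RK4 substeps per frame interval (>= 1, default 10).
#' @return Object of class `pathlines`: list with `times` (length
#'   `n_samples`), `pos` (`n_seeds x 3 x n_samples` array, mm), `frozen`
#'   and `valid` logical vectors, and the seed table.
#' @export
integrate_pathlines <- function(field, seeds, t_start, t_end, substeps = 10) {
  stopifnot(inherits(field, "velocity_field"), substeps >= 1)
  seed_tbl <- NULL
  if (is.data.frame(seeds)) {
    seed_tbl <- seeds
    seeds <- as.matrix(seeds[, c("x_mm", "y_mm", "z_mm")])
  }
  seeds <- matrix(as.numeric(seeds), ncol = 3)
  dims <- dim(field$vx)[1:3]
  hi <- (dims - 1) * field$spacing
  dtf <- field$rr_interval / field$n_frames
  h_abs <- dtf / substeps
  span <- t_end - t_start
  n_steps <- as.integer(round(abs(span) / h_abs))
  h <- if (span >= 0) h_abs else -h_abs

  n <- nrow(seeds)
  pos <- seeds
  traj <- array(NA_real_, c(n, 3, n_steps + 1))
  traj[, , 1] <- pos
  frozen <- rep(FALSE, n)
  valid <- rep(TRUE, n)
  in_grid <- function(p) {
    p[, 1] >= 0 & p[, 1] <= hi[1] & p[, 2] >= 0 & p[, 2] <= hi[2] &
      p[, 3] >= 0 & p[, 3] <= hi[3]
  }
  frozen[!in_grid(pos)] <- TRUE
  t <- t_start
  for (s in seq_len(n_steps)) {
    act <- !frozen & valid
    if (any(act)) {
      p <- pos[act, , drop = FALSE]
      # velocities in cm/s, positions in mm: 1 cm/s = 10 mm/s
      k1 <- sample_velocity(field, p, t) * 10
      k2 <- sample_velocity(field, p + h / 2 * k1, t + h / 2) * 10
      k3 <- sample_velocity(field, p + h / 2 * k2, t + h / 2) * 10
      k4 <- sample_velocity(field, p + h * k3, t + h) * 10
      newp <- p + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      bad <- !is.finite(newp[, 1] + newp[, 2] + newp[, 3])
      ok <- in_grid(newp) & !bad
      ids <- which(act)
      valid[ids[bad]] <- FALSE
      frozen[ids[!ok & !bad]] <- TRUE
      move <- ids[ok]
      pos[move, ] <- newp[ok, , drop = FALSE]
    }
    t <- t + h
    traj[, , s + 1] <- pos
  }
  structure(list(times = t_start + h * (0:n_steps), pos = traj,
                 frozen = frozen, valid = valid, seeds = seed_tbl,
                 substeps = substeps),
            class = "pathlines")
}

#' @export
print.pathlines <- function(x, ...) {
  cat("<pathlines> ", dim(x$pos)[1], " trajectories, ",
      length(x$times), " samples over [",
      format(min(x$times), digits = 3), ", ",
      format(max(x$times), digits = 3), "] s\n", sep = "")
  cat("  frozen at grid edge: ", sum(x$frozen), "; invalid: ",
      sum(!x$valid), "\n", sep = "")
  invisible(x)
}

#' Integrate a single pathline
#'
#' Convenience wrapper around [integrate_pathlines()] for one seed.
#'
#' @param field A [velocity_field()].
#' @param seed Numeric length-3 position in mm.
#' @inheritParams integrate_pathlines
#' @return Tibble `time_s`, `x_mm`, `y_mm`, `z_mm`.
#' @export
integrate_pathline <- function(field, seed, t_start, t_end, substeps = 10) {
  pl <- integrate_pathlines(field, matrix(seed, 1), t_start, t_end, substeps)
  tibble::tibble(time_s = pl$times, x_mm = pl$pos[1, 1, ],
                 y_mm = pl$pos[1, 2, ], z_mm = pl$pos[1, 3, ])
}

#' Export trajectories as a long tibble
#' @param pl A `pathlines` object.
#' @return Tibble `id`, `time_s`, `x_mm`, `y_mm`, `z_mm` suitable for CSV
#'   export and external visualization.
#' @export
pathline_table <- function(pl) {
  stopifnot(inherits(pl, "pathlines"))
  n <- dim(pl$pos)[1]; s <- dim(pl$pos)[3]
  tibble::tibble(
    id = rep(seq_len(n), s),
    time_s = rep(pl$times, each = n),
    x_mm = as.vector(pl$pos[, 1, ]),
    y_mm = as.vector(pl$pos[, 2, ]),
    z_mm = as.vector(pl$pos[, 3, ]))
}
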