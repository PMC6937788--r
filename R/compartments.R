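#' @name flow_compartments
#' @title Intraventricular flow compartments
#'
#' @description
#' End-diastolic blood is partitioned by where its pathline was at the
#' surrounding end-systoles: *direct flow* entered the LV during the
#' analyzed diastole and leaves during systole; *retained inflow* entered
#' but does not leave; *delayed ejection flow* was already inside and
#' leaves; *residual volume* stays inside throughout (at least two
#' cycles). Valid transit is through the basal region (the valve plane);
#' any pathline crossing the LV boundary at a mid-ventricular or apical
#' slice has passed through the wall and is excluded from the
#' compartments.
NULL

# inside-LV flags for a pathlines object against the cine mask: the mask
# of the temporally nearest frame is used (masks are discrete in time).
# Returns n_seeds x n_samples logical matrix.
inside_matrix <- function(pl, seg) {
  dims <- dim(seg$mask)[1:3]
  nt <- dim(seg$mask)[4]
  n <- dim(pl$pos)[1]
  ns <- dim(pl$pos)[3]
  ins <- matrix(FALSE, n, ns)
  nxyz <- prod(dims)
  mask_vec <- seg$mask
  for (s in seq_len(ns)) {
    t <- pl$times[s]
    fr <- (round(t / (attr_dtf(seg, nt))) %% nt) + 1
    p <- pl$pos[, , s, drop = FALSE]
    u <- round(sweep(matrix(p, n, 3), 2, seg$spacing, `/`))
    ok <- u[, 1] >= 0 & u[, 1] <= dims[1] - 1 &
      u[, 2] >= 0 & u[, 2] <= dims[2] - 1 &
      u[, 3] >= 0 & u[, 3] <= dims[3] - 1
    idx <- 1 + u[, 1] + dims[1] * u[, 2] + dims[1] * dims[2] * u[, 3] +
      nxyz * (fr - 1)
    ins[ok, s] <- mask_vec[idx[ok]]
  }
  ins
}

# frame interval implied by a cine mask paired with the run's rr; stored
# on the mask by track_compartments
attr_dtf <- function(seg, nt) {
  rr <- attr(seg, "rr_interval")
  if (is.null(rr)) stop("internal: mask lacks rr_interval", call. = FALSE)
  rr / nt
}

# region label of a boundary crossing at distance-from-apex `dist` (mm):
# beyond the basal-most slice = valid basal (valve-plane) transit; below
# the apical-most slice counts as apex.
region_of_dist <- function(dist, boundaries) {
  lz <- boundaries[4]
  out <- character(length(dist))
  out[dist >= boundaries[3]] <- "base"          # includes beyond-base transit
  out[dist >= boundaries[2] & dist < boundaries[3]] <- "mid"
  out[dist < boundaries[2]] <- "apex"
  out
}

# crossing regions for one trace: inside flags n x ns, positions pl$pos.
# Returns list(excluded = logical n (any mid/apex crossing),
#              ended_outside = logical n)
scan_crossings <- function(pl, ins, seg, partition) {
  n <- nrow(ins); ns <- ncol(ins)
  ax <- seg$slice_axis
  sign <- seg$apex_to_base_sign
  b <- attr(partition, "boundaries_mm")
  apex_mm <- (attr(partition, "apex_slice") - 1) * seg$spacing[ax]
  excluded <- rep(FALSE, n)
  for (s in seq_len(ns - 1)) {
    tr <- which(ins[, s] != ins[, s + 1])
    if (length(tr) == 0) next
    # crossing located at the first sample on the outside of the wall
    out_side <- ifelse(ins[tr, s], s + 1, s)
    z <- pl$pos[cbind(tr, ax, out_side)]
    dist <- (z - apex_mm) * sign
    reg <- region_of_dist(dist, b)
    excluded[tr[reg %in% c("mid", "apex")]] <- TRUE
  }
  list(excluded = excluded, ended_outside = !ins[, ns])
}

#' Classify pathlines into the four flow compartments
#'
#' Combines a forward trace (end diastole to end systole) and a backward
#' trace (end diastole back to the previous end systole) of the same
#' seeds: a pathline *entered* if it is outside the LV at the backward
#' endpoint, and *left* if it is outside at the forward endpoint.
#' Entered-and-left is direct flow, entered-only retained inflow,
#' left-only delayed ejection flow, neither residual volume. Any wall
#' crossing located in the mid-ventricular or apical region (in either
#' trace), or an invalid trajectory, excludes the pathline.
#'
#' @param forward,backward `pathlines` objects over the same seeds, from
#'   [integrate_pathlines()].
#' @param seg The [cine_mask()] (with the run's `rr_interval` attached;
#'   [track_compartments()] does this).
#' @param partition A [partition_regions()] result.
#' @return Factor of length `n_seeds` with levels `direct`, `retained`,
#'   `delayed`, `residual`, `excluded`.
#' @export
classify_pathlines <- function(forward, backward, seg, partition) {
  ins_f <- inside_matrix(forward, seg)
  ins_b <- inside_matrix(backward, seg)
  cf <- scan_crossings(forward, ins_f, seg, partition)
  cb <- scan_crossings(backward, ins_b, seg, partition)
  excluded <- cf$excluded | cb$excluded | !forward$valid | !backward$valid
  entered <- cb$ended_outside
  left <- cf$ended_outside
  lab <- ifelse(excluded, "excluded",
         ifelse(entered & left, "direct",
         ifelse(entered, "retained",
         ifelse(left, "delayed", "residual"))))
  factor(lab, levels = c("direct", "retained", "delayed", "residual",
                         "excluded"))
}

#' Compartment volume fractions from pathline labels
#'
#' Each compartment's percentage is the blood volume represented by its
#' pathlines over the volume of all non-excluded pathlines; the excluded
#' percentage is over all emitted pathlines. The four compartment
#' percentages sum to 100 by construction.
#'
#' @param labels Factor from [classify_pathlines()].
#' @param seed_volumes Volume represented by each pathline (mL); a single
#'   value is recycled.
#' @return One-row tibble `direct_pct`, `retained_pct`, `delayed_pct`,
#'   `residual_pct`, `excluded_pct`, `n_pathlines`, `n_excluded`.
#' @export
compartment_fractions <- function(labels, seed_volumes = 1) {
  labels <- factor(labels, levels = c("direct", "retained", "delayed",
                                      "residual", "excluded"))
  if (length(seed_volumes) == 1) {
    seed_volumes <- rep(seed_volumes, length(labels))
  }
  stopifnot(length(seed_volumes) == length(labels))
  vol <- tapply(seed_volumes, labels, sum, default = 0)
  keep <- sum(vol[c("direct", "retained", "delayed", "residual")])
  if (keep <= 0) {
    stop("all pathlines were excluded; no compartment volume to report",
         call. = FALSE)
  }
  tibble::tibble(
    direct_pct = 100 * vol[["direct"]] / keep,
    retained_pct = 100 * vol[["retained"]] / keep,
    delayed_pct = 100 * vol[["delayed"]] / keep,
    residual_pct = 100 * vol[["residual"]] / keep,
    excluded_pct = 100 * vol[["excluded"]] / sum(vol),
    n_pathlines = length(labels),
    n_excluded = sum(labels == "excluded"))
}

#' Full pathline compartment analysis of one subject
#'
#' Seeds the end-diastolic blood pool, traces pathlines forward to end
#' systole and backward to the previous end systole (so the whole cycle
#' is covered), classifies them and returns the compartment fractions.
#' ED and ES default to the frames of maximum and minimum cavity volume.
#'
#' @param field A [velocity_field()] (for noise-sensitive data, pass the
#'   dedicated low-noise reconstruction here).
#' @param seg A [cine_mask()] on the same grid.
#' @param partition Optional [partition_regions()]; recomputed if absent.
#' @param ed_frame,es_frame Optional frame overrides.
#' @param density Seeding density, see [seed_pathlines()].
#' @param substeps RK4 substeps per frame interval.
#' @param keep_trajectories Keep the integrated traces in the result?
#' @return List of class `compartment_analysis`: `fractions` (tibble),
#'   `labels`, `seeds`, `ed_frame`, `es_frame`, and optionally
#'   `forward`/`backward` traces.
#' @export
track_compartments <- function(field, seg, partition = NULL,
                               ed_frame = NULL, es_frame = NULL,
                               density = 1, substeps = 10,
                               keep_trajectories = FALSE) {
  stopifnot(inherits(field, "velocity_field"), inherits(seg, "cine_mask"))
  check_same_grid(field, seg)
  counts <- apply(seg$mask, 4, sum)
  ed_frame <- ed_frame %||% which.max(counts)
  es_frame <- es_frame %||% which.min(counts)
  if (ed_frame == es_frame) {
    stop("ED and ES frames coincide; specify `ed_frame`/`es_frame` ",
         "explicitly for volume-static data", call. = FALSE)
  }
  if (is.null(partition)) partition <- partition_regions(seg, ed_frame)
  nt <- field$n_frames
  dtf <- field$rr_interval / nt
  t_ed <- (ed_frame - 1) * dtf
  fwd_frames <- ((es_frame - ed_frame) %% nt)
  t_es_next <- t_ed + fwd_frames * dtf
  t_es_prev <- t_es_next - field$rr_interval
  seeds <- seed_pathlines(seg, ed_frame, density)
  attr(seg, "rr_interval") <- field$rr_interval
  fwd <- integrate_pathlines(field, seeds, t_ed, t_es_next, substeps)
  bwd <- integrate_pathlines(field, seeds, t_ed, t_es_prev, substeps)
  labels <- classify_pathlines(fwd, bwd, seg, partition)
  fr <- compartment_fractions(labels, seeds$volume_ml)
  out <- list(fractions = fr, labels = labels, seeds = seeds,
              ed_frame = ed_frame, es_frame = es_frame,
              partition = partition)
  if (keep_trajectories) {
    out$forward <- fwd
    out$backward <- bwd
  }
  structure(out, class = "compartment_analysis")
}

#' @export
print.compartment_analysis <- function(x, ...) {
  f <- x$fractions
  cat("<compartment_analysis> ", f$n_pathlines, " pathlines (ED frame ",
      x$ed_frame, " -> ES frame ", x$es_frame, ")\n", sep = "")
  cat(sprintf("  direct %.1f%% | retained %.1f%% | delayed %.1f%% | residual %.1f%% (excluded %.1f%%)\n",
              f$direct_pct, f$retained_pct, f$delayed_pct, f$residual_pct,
              f$excluded_pct))
  invisible(x)
}
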