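#' Run the full per-subject analysis
#'
#' Composes the pipeline stages on one subject's data: background
#' phase-error correction, regional partition, through-plane flow curves
#' and peaks, kinetic energy indexed to EDV, pathline compartment
#' analysis, and cavity-volume function metrics. The result is a one-row
#' tibble carrying the 11 LV flow parameters (peak systolic and diastolic
#' flow per region, KEi_EDV, four compartment percentages) plus the
#' global function metrics and QC quantities.
#'
#' @param field A [velocity_field()].
#' @param seg A [cine_mask()] on the same grid.
#' @param heart_rate Heart rate in bpm (for cardiac output); optional.
#' @param id Subject identifier carried into the record.
#' @param correct_phase Apply background phase-error correction?
#' @param sd_percentile Static-tissue percentile for
#'   [estimate_static_mask()].
#' @param static_mask Optional known static-tissue mask (3-D logical),
#'   overriding the estimate.
#' @param pathline_field Optional second velocity field (e.g. a low-noise
#'   reconstruction on the same grid) used for pathline tracking; it is
#'   phase-corrected independently.
#' @param density,substeps Pathline parameters, see
#'   [track_compartments()].
#' @param ed_frame,es_frame Optional frame overrides.
#' @return One-row tibble (the subject record).
#' @export
analyze_subject <- function(field, seg, heart_rate = NULL, id = NA_character_,
                            correct_phase = TRUE, sd_percentile = 30,
                            static_mask = NULL, pathline_field = NULL,
                            density = 1, substeps = 10,
                            ed_frame = NULL, es_frame = NULL) {
  stopifnot(inherits(field, "velocity_field"), inherits(seg, "cine_mask"))
  check_same_grid(field, seg)
  apply_correction <- function(f) {
    sm <- static_mask %||% estimate_static_mask(f, sd_percentile)
    correct_background_phase(f, fit_background_phase(f, sm))
  }
  if (correct_phase) {
    field <- apply_correction(field)
    if (!is.null(pathline_field)) pathline_field <- apply_correction(pathline_field)
  }
  vf <- cavity_volumes(seg, heart_rate)
  ed_frame <- ed_frame %||% vf$ed_frame
  es_frame <- es_frame %||% vf$es_frame
  partition <- partition_regions(seg, ed_frame)
  curves <- throughplane_flow(field, seg, partition)
  peaks <- peak_flows(curves)
  ke <- kinetic_energy(field, seg, vf$edv_ml)
  cp <- track_compartments(pathline_field %||% field, seg, partition,
                           ed_frame = ed_frame, es_frame = es_frame,
                           density = density, substeps = substeps)
  pk <- function(reg, what) peaks[[what]][peaks$region == reg]
  tibble::tibble(
    id = id,
    heart_rate = heart_rate %||% NA_real_,
    peak_systolic_base = pk("base", "peak_systolic"),
    peak_systolic_mid = pk("mid", "peak_systolic"),
    peak_systolic_apex = pk("apex", "peak_systolic"),
    peak_diastolic_base = pk("base", "peak_diastolic"),
    peak_diastolic_mid = pk("mid", "peak_diastolic"),
    peak_diastolic_apex = pk("apex", "peak_diastolic"),
    kei_edv = ke$kei_edv,
    direct_pct = cp$fractions$direct_pct,
    retained_pct = cp$fractions$retained_pct,
    delayed_pct = cp$fractions$delayed_pct,
    residual_pct = cp$fractions$residual_pct,
    excluded_pct = cp$fractions$excluded_pct,
    edv_ml = vf$edv_ml, esv_ml = vf$esv_ml, sv_ml = vf$sv_ml,
    ef_pct = vf$ef_pct, co_l_min = vf$co_l_min,
    ke_avg_uj = ke$ke_avg_uj,
    ed_frame = ed_frame, es_frame = es_frame)
}

#' Analyze one subject from an on-disk dataset
#'
#' Reads a subject directory written by [materialize_cohort()] (velocity
#' component NIfTIs, mask NIfTI, `meta.yaml` with `id`, `rr_interval`,
#' `slice_axis`, `apex_to_base_sign`) and runs [analyze_subject()].
#'
#' @param dir Subject directory.
#' @param ... Passed to [analyze_subject()].
#' @return One-row tibble.
#' @export
analyze_subject_files <- function(dir, ...) {
  meta <- yaml::read_yaml(file.path(dir, "meta.yaml"))
  field <- read_velocity_series(
    file.path(dir, paste0("velocity_", c("vx", "vy", "vz"), ".nii.gz")),
    rr_interval = meta$rr_interval)
  seg <- read_mask_series(file.path(dir, "mask.nii.gz"),
                          slice_axis = meta$slice_axis %||% 3,
                          apex_to_base_sign = meta$apex_to_base_sign %||% 1)
  analyze_subject(field, seg,
                  heart_rate = if (!is.null(meta$rr_interval)) 60 / meta$rr_interval else NULL,
                  id = meta$id %||% basename(dir), ...)
}

#' Run the cohort-level analysis
#'
#' Analyzes every subject directory (a failing subject is skipped with a
#' warning and listed in the result, so one corrupt dataset does not
#' abort the cohort), joins the per-subject flow parameters to the
#' covariate table, and produces the cohort tables: demographics
#' comparison, per-group median ± IQR descriptives, the
#' covariate-adjusted group-effect table for the 11 flow parameters, and
#' Spearman correlations of regional flow against traditional CMR
#' measures in the patient group. With fewer than 2 subjects per group
#' only descriptives are produced, with a warning.
#'
#' @param subject_dirs Character vector of subject directories, or the
#'   tibble returned by [materialize_cohort()].
#' @param covariates Tibble with `id`, `group`, `age`, `sex`,
#'   `heart_rate` (e.g. from [simulate_cohort()]).
#' @param out_dir Optional directory: result tables are written as CSV
#'   together with a YAML run manifest.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @param ... Passed to [analyze_subject_files()] /
#'   [analyze_subject()] (e.g. `density`, `substeps`, `correct_phase`).
#' @return List of class `cohort_analysis`: `records`, `demographics`,
#'   `descriptives`, `group_effects`, `correlations`, `skipped`,
#'   `manifest`.
#' @export
analyze_cohort <- function(subject_dirs, covariates, out_dir = NULL,
                           seed = NULL, ...) {
  if (is.data.frame(subject_dirs)) subject_dirs <- subject_dirs$dir
  if (length(subject_dirs) == 0) stop("no subject directories given", call. = FALSE)
  opts <- list(...)
  res <- purrr::map(subject_dirs, function(d) {
    tryCatch(analyze_subject_files(d, ...), error = function(e) {
      warning("subject '", basename(d), "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
  })
  skipped <- basename(subject_dirs)[purrr::map_lgl(res, is.null)]
  records <- dplyr::bind_rows(purrr::compact(res))
  if (nrow(records) == 0) stop("no subject could be analyzed", call. = FALSE)
  records <- dplyr::left_join(
    records |> dplyr::select(-"heart_rate"),
    covariates |> dplyr::select(dplyr::any_of(
      c("id", "group", "age", "sex", "heart_rate"))),
    by = "id")
  params <- intersect(flow_parameter_names(), names(records))
  n_per_group <- table(records$group)
  comparable <- length(n_per_group) == 2 && all(n_per_group >= 2)
  demographics <- NULL; effects <- NULL; correlations <- NULL
  descriptives <- describe_by_group(records, params)
  if (comparable) {
    demographics <- compare_demographics(records)
    effects <- tryCatch(group_effects(records, params), error = function(e) {
      warning("group model could not be fitted: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    ami <- records[records$group == "AMI", ]
    flow_regional <- grep("^peak_", params, value = TRUE)
    cmr <- intersect(c("heart_rate", "sv_ml", "co_l_min", "ef_pct", "edv_ml"),
                     names(ami))
    if (nrow(ami) >= 3) {
      correlations <- tryCatch(
        correlate_flow_cmr(ami, flow_regional, cmr),
        error = function(e) NULL)
    }
  } else {
    warning("fewer than 2 subjects in a group: descriptives only, ",
            "comparison skipped", call. = FALSE)
  }
  manifest <- list(
    package = "lvflow",
    version = as.character(utils::packageVersion("lvflow")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    n_subjects = nrow(records),
    n_skipped = length(skipped),
    seed = seed,
    options = opts,
    config_hash = rlang::hash(list(subject_dirs, opts, seed)))
  out <- structure(list(records = records, demographics = demographics,
                        descriptives = descriptives, group_effects = effects,
                        correlations = correlations, skipped = skipped,
                        manifest = manifest),
                   class = "cohort_analysis")
  if (!is.null(out_dir)) {
    tables <- purrr::compact(list(demographics = demographics,
                                  descriptives = descriptives,
                                  group_effects = effects,
                                  correlations = correlations))
    write_results(records, tables, out_dir)
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  out
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("<cohort_analysis> ", nrow(x$records), " subjects analyzed",
      if (length(x$skipped) > 0) paste0(" (", length(x$skipped), " skipped)"),
      "\n", sep = "")
  if (!is.null(x$group_effects)) {
    cat("  adjusted group effects:\n")
    print(x$group_effects, n = Inf)
  }
  invisible(x)
}
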