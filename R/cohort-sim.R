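#' Names of the 11 LV flow parameters
#'
#' Peak systolic and diastolic through-plane flow in each of the three
#' regions (L/min), whole-LV kinetic energy indexed to EDV (uJ/mL), and
#' the four flow-compartment percentages.
#' @return Character vector of length 11.
#' @export
flow_parameter_names <- function() {
  c("peak_systolic_base", "peak_systolic_mid", "peak_systolic_apex",
    "peak_diastolic_base", "peak_diastolic_mid", "peak_diastolic_apex",
    "kei_edv", "direct_pct", "retained_pct", "delayed_pct", "residual_pct")
}

# control-group typical values (medians reported for healthy controls)
default_baselines <- function() {
  stats::setNames(
    c(16.2, 8.5, 2.2, 18.6, 12, 3.1, 11.3, 58, 15, 16, 7),
    flow_parameter_names())
}

# adjusted AMI-minus-control differences used as default planted effects
default_group_effects <- function() {
  stats::setNames(
    c(-2.1, -3.9, -1.4, 1.1, -1.6, -2.4, -0.9, -41, 12, 8, 21),
    flow_parameter_names())
}

# covariate effect coefficients per outcome: rows = age (per year),
# heart_rate (per bpm), sex_m (M vs F). Chosen once to give measurable
# confounding given the group covariate gaps; see the methods vignette.
default_covariate_coefs <- function() {
  p <- flow_parameter_names()
  is_pct <- grepl("_pct$", p)
  m <- rbind(age = ifelse(is_pct, -0.05, -0.02),
             heart_rate = ifelse(is_pct, -0.1, -0.05),
             sex_m = ifelse(is_pct, 1, 0.5))
  colnames(m) <- p
  m
}

#' Simulate a two-group 4D-flow cohort with planted effects
#'
#' Draws per-subject covariates with group-specific distributions
#' (controls younger and slower-hearted than AMI patients, emulating a
#' retrospectively combined cohort), then generates each of the 11 flow
#' parameters as
#' `baseline + covariate effects + planted group effect + Gaussian noise`.
#' Covariate effects are centred at the control-group covariate means, so
#' the control mean stays near `baseline` while the group covariate gaps
#' confound the unadjusted comparison — the structure the
#' covariate-adjusted model of [group_model()] is designed to undo.
#'
#' @param n_control,n_ami Group sizes (>= 2 each). Defaults 19 and 12.
#' @param effects Named numeric of planted adjusted group differences
#'   (AMI minus control) per flow parameter; default
#'   `default_group_effects()`.
#' @param covariate_coefs 3 x 11 matrix of age / heart-rate / sex effects
#'   per outcome; default `default_covariate_coefs()`. Use 0 to switch
#'   confounding off.
#' @param covariate_means,covariate_sds Named lists giving per-group age
#'   and heart-rate distributions. Defaults: controls 40 (SD 16) years,
#'   60 (SD 10) bpm; AMI 66 (SD 12) years, 79 (SD 15) bpm.
#' @param p_male Per-group probability of male sex; defaults 10/19 and
#'   11/12.
#' @param residual_sd Residual noise SD, one value recycled over
#'   parameters or a named vector. Default 1.
#' @param baselines Named numeric of control-level parameter values.
#' @param seed RNG seed.
#' @return A tibble with columns `id`, `group` (`control`/`AMI`), `age`,
#'   `sex` (`F`/`M`), `heart_rate`, and the 11 flow parameters.
#' @export
#' @examples
#' co <- simulate_cohort(seed = 1)
#' dplyr::count(co, group)
simulate_cohort <- function(n_control = 19, n_ami = 12,
                            effects = default_group_effects(),
                            covariate_coefs = default_covariate_coefs(),
                            covariate_means = list(
                              control = c(age = 40, heart_rate = 60),
                              AMI = c(age = 66, heart_rate = 79)),
                            covariate_sds = list(
                              control = c(age = 16, heart_rate = 10),
                              AMI = c(age = 12, heart_rate = 15)),
                            p_male = c(control = 10 / 19, AMI = 11 / 12),
                            residual_sd = 1,
                            baselines = default_baselines(),
                            seed = NULL) {
  stopifnot(n_control >= 2, n_ami >= 2)
  if (!is.null(seed)) set.seed(seed)
  pars <- flow_parameter_names()
  effects <- effects[pars]
  if (any(is.na(effects))) stop("`effects` must name all 11 flow parameters",
                                call. = FALSE)
  if (length(residual_sd) == 1) {
    residual_sd <- stats::setNames(rep(residual_sd, 11), pars)
  }
  n <- n_control + n_ami
  group <- rep(c("control", "AMI"), c(n_control, n_ami))
  draw <- function(var) {
    vapply(group, function(g) {
      stats::rnorm(1, covariate_means[[g]][var], covariate_sds[[g]][var])
    }, numeric(1))
  }
  age <- pmax(draw("age"), 18)
  hr <- pmax(draw("heart_rate"), 35)
  sex <- ifelse(stats::runif(n) < p_male[group], "M", "F")
  ref <- covariate_means$control
  ref_pm <- p_male[["control"]]
  out <- tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    group = group, age = age, sex = sex, heart_rate = hr)
  for (p in pars) {
    out[[p]] <- baselines[[p]] +
      covariate_coefs["age", p] * (age - ref[["age"]]) +
      covariate_coefs["heart_rate", p] * (hr - ref[["heart_rate"]]) +
      covariate_coefs["sex_m", p] * ((sex == "M") - ref_pm) +
      effects[[p]] * (group == "AMI") +
      stats::rnorm(n, 0, residual_sd[[p]])
  }
  out
}

#' Simulate per-subject 17-segment infarct transmurality scores
#'
#' Draws independent AHA 17-segment transmurality scores on the 5-point
#' scale (0 = no infarction up to 4 = > 75% transmural) from a categorical
#' distribution.
#'
#' @param n_subjects Number of subjects.
#' @param prob Probabilities over scores 0..4 (length 5, summing to 1).
#'   Default is weighted towards no/low transmurality.
#' @param seed RNG seed.
#' @return Integer matrix `n_subjects` x 17.
#' @export
simulate_infarct_scores <- function(n_subjects,
                                    prob = c(0.6, 0.1, 0.1, 0.1, 0.1),
                                    seed = NULL) {
  if (length(prob) != 5 || any(prob < 0) || abs(sum(prob) - 1) > 1e-8) {
    stop("`prob` must be 5 nonnegative probabilities over scores 0..4 ",
         "summing to 1", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:4, n_subjects * 17, replace = TRUE, prob = prob),
         nrow = n_subjects, ncol = 17,
         dimnames = list(NULL, paste0("seg", 1:17)))
}

#' Materialize phantom image datasets for a simulated cohort
#'
#' Writes one ellipsoid-phantom 4D-flow dataset (velocity components +
#' cine mask, NIfTI) per cohort row, scaling the phantom's contraction
#' amplitude by group so AMI subjects carry genuinely reduced flow, and
#' setting the cycle duration from the subject's heart rate. Used for
#' end-to-end pipeline runs on purely synthetic data.
#'
#' @param cohort Tibble from [simulate_cohort()] (columns `id`, `group`,
#'   `heart_rate` used).
#' @param dir Output directory; one subdirectory per subject.
#' @param spacing Voxel size in mm (default 2.5: the coarse pathline-style
#'   grid).
#' @param n_frames Frames per cycle.
#' @param alpha_by_group Named contraction fractions, default control
#'   0.25, AMI 0.15.
#' @param R0,L Phantom geometry, cm.
#' @param noise_sd Velocity noise SD, cm/s.
#' @param seed Base RNG seed; subject `i` uses `seed + i`.
#' @return Tibble `id`, `dir` of the written subject datasets.
#' @export
materialize_cohort <- function(cohort, dir, spacing = 2.5, n_frames = 20,
                               alpha_by_group = c(control = 0.25, AMI = 0.15),
                               R0 = 2, L = 8, noise_sd = 0, seed = 0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    id <- cohort$id[i]
    subj_dir <- file.path(dir, id)
    ph <- ellipsoid_phantom(
      R0 = R0, L = L, alpha = alpha_by_group[[cohort$group[i]]],
      n_frames = n_frames, rr_interval = 60 / cohort$heart_rate[i],
      spacing = spacing, noise_sd = noise_sd,
      seed = if (noise_sd > 0) seed + i else NULL)
    write_velocity_series(ph$field, subj_dir)
    write_mask_series(ph$seg, file.path(subj_dir, "mask.nii.gz"))
    yaml::write_yaml(list(id = id, rr_interval = ph$field$rr_interval,
                          slice_axis = 3, apex_to_base_sign = 1),
                     file.path(subj_dir, "meta.yaml"))
    tibble::tibble(id = id, dir = subj_dir)
  })
  dplyr::bind_rows(rows)
}
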