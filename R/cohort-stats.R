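#' Covariate-adjusted group comparison of one flow parameter
#'
#' Fits the multivariable ordinary-least-squares model
#' `outcome ~ group + age + sex + heart_rate` with group coded AMI = 1,
#' control = 0 and sex coded M = 1, F = 0 (so a flow reduction in
#' patients appears as a negative group coefficient). The adjusted group
#' difference is the group coefficient; its CI and p-value come from the
#' t distribution with residual degrees of freedom. No multiple-testing
#' correction is applied when the model is run over several parameters —
#' each parameter is tested at its own alpha, which callers should keep
#' in mind when reading many rows.
#'
#' @param cohort Tibble with columns `group` (`control`/`AMI`), `age`,
#'   `sex` (`F`/`M`), `heart_rate` and the outcome. At least 6 complete
#'   rows with both groups represented.
#' @param outcome Name of the outcome column.
#' @param conf_level Confidence level, default 0.95.
#' @return Object of class `group_effect` wrapping the `lm` fit, with
#'   [generics::tidy()] and [generics::glance()] methods.
#' @export
#' @examples
#' co <- simulate_cohort(seed = 1)
#' fit <- group_model(co, "peak_systolic_mid")
#' generics::tidy(fit)
group_model <- function(cohort, outcome, conf_level = 0.95) {
  need <- c("group", "age", "sex", "heart_rate", outcome)
  miss <- setdiff(need, names(cohort))
  if (length(miss) > 0) {
    stop("cohort lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  d <- cohort[stats::complete.cases(cohort[, need]), need]
  if (nrow(d) < 6) {
    stop("need at least 6 subjects with complete covariates; got ",
         nrow(d), call. = FALSE)
  }
  if (length(unique(d$group)) < 2) {
    stop("both groups must be represented", call. = FALSE)
  }
  md <- tibble::tibble(
    y = d[[outcome]],
    group_ami = as.numeric(d$group == "AMI"),
    age = d$age,
    sex_m = as.numeric(d$sex == "M"),
    heart_rate = d$heart_rate)
  fit <- stats::lm(y ~ group_ami + age + sex_m + heart_rate, data = md)
  co <- stats::coef(fit)
  if (any(is.na(co))) {
    stop("singular design: column(s) ",
         paste(names(co)[is.na(co)], collapse = ", "),
         " are collinear (e.g. a single-sex cohort)", call. = FALSE)
  }
  structure(list(fit = fit, outcome = outcome, conf_level = conf_level,
                 n = nrow(d)),
            class = "group_effect")
}

#' @importFrom generics tidy
#' @method tidy group_effect
#' @export
tidy.group_effect <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  ci <- stats::confint(x$fit, level = x$conf_level)
  tibble::tibble(
    term = rownames(sm),
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    statistic = unname(sm[, "t value"]),
    p_value = unname(sm[, "Pr(>|t|)"]),
    conf_low = unname(ci[, 1]),
    conf_high = unname(ci[, 2]))
}

#' @method glance group_effect
#' @export
glance.group_effect <- function(x, ...) {
  td <- tidy(x)
  g <- td[td$term == "group_ami", ]
  tibble::tibble(
    parameter = x$outcome,
    delta_mi = g$estimate,
    conf_low = g$conf_low,
    conf_high = g$conf_high,
    p_value = g$p_value,
    n = x$n)
}

#' @export
print.group_effect <- function(x, ...) {
  g <- glance(x)
  cat("<group_effect> ", x$outcome, ": adjusted AMI-control difference ",
      format(g$delta_mi, digits = 3), " [",
      format(g$conf_low, digits = 3), ", ", format(g$conf_high, digits = 3),
      "], p = ", format(g$p_value, digits = 2), " (n = ", g$n, ")\n",
      sep = "")
  invisible(x)
}

#' Adjusted group effects for a set of flow parameters
#'
#' Runs [group_model()] over each outcome and stacks the one-row
#' summaries, producing the parameter / adjusted difference / CI /
#' p-value table for the cohort.
#'
#' @param cohort As in [group_model()].
#' @param outcomes Character vector of outcome columns; defaults to the
#'   11 LV flow parameters present in `cohort`.
#' @inheritParams group_model
#' @return Tibble with columns `parameter`, `delta_mi`, `conf_low`,
#'   `conf_high`, `p_value`, `n`.
#' @export
group_effects <- function(cohort, outcomes = NULL, conf_level = 0.95) {
  outcomes <- outcomes %||% intersect(flow_parameter_names(), names(cohort))
  if (length(outcomes) == 0) stop("no outcome columns found", call. = FALSE)
  purrr::map_dfr(outcomes, function(p) {
    glance(group_model(cohort, p, conf_level))
  })
}

#' Spearman rank correlation
#'
#' `rho` is the Pearson correlation of mid-ranks (average ranks on ties).
#' For n <= 10 without ties the two-sided p-value is exact (distribution
#' of the rank statistic); otherwise the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` is used.
#'
#' @param x,y Paired numeric vectors, n >= 3 after removing incomplete
#'   pairs.
#' @return One-row tibble `rho`, `p_value`, `n`, `method`.
#' @export
#' @examples
#' spearman_corr(1:3, c(3, 2, 1))   # rho = -1
spearman_corr <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rho is undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 10 && !ties) {
    p <- stats::cor.test(x, y, method = "spearman", exact = TRUE)$p.value
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- if (!is.finite(tstat)) 0 else 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  }
  tibble::tibble(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Descriptive summary of one variable
#'
#' Median with inter-quartile range (Q3 - Q1, quartiles by linear
#' interpolation between order statistics) for skewed flow parameters, or
#' mean with sample (n - 1) standard deviation for demographics.
#'
#' @param values Nonempty numeric vector (NAs dropped).
#' @param style `"median_iqr"` or `"mean_sd"`.
#' @return One-row tibble: `n` plus `median`/`iqr` or `mean`/`sd`.
#' @export
describe <- function(values, style = c("median_iqr", "mean_sd")) {
  style <- match.arg(style)
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no non-missing values", call. = FALSE)
  if (style == "median_iqr") {
    q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    tibble::tibble(n = length(values), median = q[2], iqr = q[3] - q[1])
  } else {
    tibble::tibble(n = length(values), mean = mean(values),
                   sd = stats::sd(values))
  }
}

#' Compare demographics between groups
#'
#' Welch (unequal-variance) two-sample t-tests for continuous variables
#' and a chi-squared test without continuity correction for the sex
#' proportion. A zero-variance variable yields `NaN` with a warning
#' rather than an error.
#'
#' @param cohort Tibble with `group` and the variables.
#' @param continuous Continuous variable names; defaults to the numeric
#'   columns among `age`, `heart_rate` and any others present except the
#'   flow parameters.
#' @return Tibble `variable`, `test`, `statistic`, `p_value`, plus the
#'   per-group means for continuous variables.
#' @export
compare_demographics <- function(cohort, continuous = NULL) {
  stopifnot("group" %in% names(cohort))
  g <- cohort$group
  if (length(unique(g)) < 2) stop("both groups must be nonempty", call. = FALSE)
  if (is.null(continuous)) {
    continuous <- intersect(c("age", "heart_rate", "weight"), names(cohort))
  }
  rows <- purrr::map_dfr(continuous, function(v) {
    x <- cohort[[v]][g == "control"]; y <- cohort[[v]][g == "AMI"]
    if (stats::sd(c(x, y)) == 0 || (stats::sd(x) == 0 && stats::sd(y) == 0)) {
      warning("variable '", v, "' has zero variance; p is NaN", call. = FALSE)
      return(tibble::tibble(variable = v, test = "welch_t",
                            statistic = NaN, p_value = NaN,
                            mean_control = mean(x), mean_ami = mean(y)))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    tibble::tibble(variable = v, test = "welch_t",
                   statistic = unname(tt$statistic), p_value = tt$p.value,
                   mean_control = mean(x), mean_ami = mean(y))
  })
  if ("sex" %in% names(cohort)) {
    tab <- table(g, cohort$sex)
    if (ncol(tab) < 2) {
      warning("single-sex cohort; sex comparison is NaN", call. = FALSE)
      chi <- list(statistic = NaN, p.value = NaN)
    } else {
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    }
    rows <- dplyr::bind_rows(rows, tibble::tibble(
      variable = "sex", test = "chi_squared",
      statistic = unname(chi$statistic), p_value = chi$p.value,
      mean_control = NA_real_, mean_ami = NA_real_))
  }
  rows
}

#' Correlate flow parameters with other CMR measures
#'
#' Spearman rank correlation of each flow parameter against each CMR
#' measure over the given rows (typically the patient group only),
#' producing the long form of a flow-by-measure rho/p matrix.
#'
#' @param cohort Tibble holding both sets of columns.
#' @param flow_vars,cmr_vars Column names to correlate.
#' @return Tibble `flow_parameter`, `measure`, `rho`, `p_value`, `n`.
#' @export
correlate_flow_cmr <- function(cohort, flow_vars, cmr_vars) {
  tidyr::expand_grid(flow_parameter = flow_vars, measure = cmr_vars) |>
    purrr::pmap_dfr(function(flow_parameter, measure) {
      sc <- spearman_corr(cohort[[flow_parameter]], cohort[[measure]])
      tibble::tibble(flow_parameter = flow_parameter, measure = measure,
                     rho = sc$rho, p_value = sc$p_value, n = sc$n)
    })
}

#' Median ± IQR per group for a set of parameters
#' @param cohort Tibble with `group` and the parameter columns.
#' @param params Parameter column names.
#' @return Tibble `parameter`, `group`, `n`, `median`, `iqr`.
#' @export
describe_by_group <- function(cohort, params = NULL) {
  params <- params %||% intersect(flow_parameter_names(), names(cohort))
  tidyr::expand_grid(parameter = params,
                     group = unique(cohort$group)) |>
    purrr::pmap_dfr(function(parameter, group) {
      d <- describe(cohort[[parameter]][cohort$group == group])
      tibble::tibble(parameter = parameter, group = group, n = d$n,
                     median = d$median, iqr = d$iqr)
    })
}
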