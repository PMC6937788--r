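null_cohort <- function(n1 = 19, n2 = 12, seed = NULL) {
  simulate_cohort(n_control = n1, n_ami = n2,
                  effects = setNames(rep(0, 11), flow_parameter_names()),
                  residual_sd = 1, seed = seed)
}

test_that("group_model reports the adjusted difference with a consistent CI", {
  co <- simulate_cohort(seed = 51)
  fit <- group_model(co, "residual_pct")
  g <- glance(fit)
  expect_true(g$conf_low <= g$delta_mi && g$delta_mi <= g$conf_high)
  expect_true(g$p_value > 0 && g$p_value <= 1)
  expect_equal(g$n, 31)
  td <- tidy(fit)
  expect_setequal(td$term, c("(Intercept)", "group_ami", "age", "sex_m",
                             "heart_rate"))
})

test_that("an exactly linear outcome gives zero residuals and a zero-width CI", {
  co <- null_cohort(seed = 52)
  co$linear <- 2 + 0.5 * co$age - 0.1 * co$heart_rate + 3 * (co$sex == "M") -
    1.5 * (co$group == "AMI")
  fit <- group_model(co, "linear")
  g <- suppressWarnings(glance(fit))   # lm warns on an exactly perfect fit
  expect_equal(g$delta_mi, -1.5, tolerance = 1e-8)
  expect_lt(g$conf_high - g$conf_low, 1e-8)
})

test_that("with group-balanced covariates the adjusted effect is the mean difference", {
  # identical covariate sets in both groups: group is orthogonal to them
  base <- tibble::tibble(age = c(40, 50, 60, 70), sex = c("F", "M", "F", "M"),
                         heart_rate = c(55, 72, 61, 85))
  co <- dplyr::bind_rows(
    dplyr::mutate(base, group = "control"),
    dplyr::mutate(base, group = "AMI"))
  set.seed(53)
  co$y <- rnorm(8)
  fit <- group_model(co, "y")
  plain_diff <- mean(co$y[co$group == "AMI"]) - mean(co$y[co$group == "control"])
  expect_equal(glance(fit)$delta_mi, plain_diff, tolerance = 1e-10)
})

test_that("a single-sex cohort is reported as a collinear design", {
  co <- null_cohort(seed = 54)
  co$sex <- "M"
  expect_error(group_model(co, "direct_pct"), "sex_m")
})

test_that("group_effects stacks one row per parameter", {
  co <- simulate_cohort(seed = 55)
  ge <- group_effects(co)
  expect_equal(nrow(ge), 11)
  expect_setequal(ge$parameter, flow_parameter_names())
  expect_true(all(ge$conf_low <= ge$delta_mi & ge$delta_mi <= ge$conf_high))
})

test_that("spearman rho handles reversals, monotone maps and ties", {
  expect_equal(spearman_corr(1:3, c(3, 2, 1))$rho, -1)
  x <- c(0.5, 1, 2, 3.5, 7)
  expect_equal(spearman_corr(x, x^2)$rho, 1)         # monotone invariance
  set.seed(56)
  a <- rnorm(25); b <- a + rnorm(25)
  expect_equal(spearman_corr(a, b)$rho,
               spearman_corr(exp(a), b^3 + 5 * b)$rho)  # strictly monotone
  expect_equal(spearman_corr(c(1, 1, 2, 3), c(1, 2, 3, 4))$rho,
               cor(rank(c(1, 1, 2, 3)), rank(c(1, 2, 3, 4))))
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("spearman p-values agree with a permutation oracle at n = 12", {
  set.seed(57)
  x <- rnorm(12); y <- x + rnorm(12, sd = 2)
  got <- spearman_corr(x, y)
  rho_obs <- got$rho
  perm <- replicate(20000, {
    abs(cor(rank(x), rank(sample(y)))) >= abs(rho_obs) - 1e-12
  })
  expect_lt(abs(got$p_value - mean(perm)), 0.02)
})

test_that("descriptives match hand arithmetic", {
  d <- describe(c(1, 2, 3, 4, 5))
  expect_equal(d$median, 3)
  expect_equal(d$iqr, 2)
  d1 <- describe(5)
  expect_equal(d1$median, 5)
  expect_equal(d1$iqr, 0)
  set.seed(58)
  ms <- describe(rnorm(1e4, 60, 10), style = "mean_sd")
  expect_equal(ms$mean, 60, tolerance = 0.02)
  expect_equal(ms$sd, 10, tolerance = 0.02)
})

test_that("identical groups give t statistics of 0 and chi-squared of 0", {
  co <- tibble::tibble(
    group = rep(c("control", "AMI"), each = 4),
    age = rep(c(30, 40, 50, 60), 2),
    heart_rate = rep(c(55, 60, 65, 70), 2),
    sex = rep(c("F", "F", "M", "M"), 2))
  cmp <- compare_demographics(co)
  tt <- cmp[cmp$test == "welch_t", ]
  expect_equal(tt$statistic, rep(0, nrow(tt)))
  expect_equal(tt$p_value, rep(1, nrow(tt)))
  expect_equal(cmp$statistic[cmp$variable == "sex"], 0)
})

test_that("well-separated groups are detected with high power", {
  set.seed(59)
  hits <- replicate(40, {
    co <- tibble::tibble(
      group = rep(c("control", "AMI"), each = 50),
      age = c(rnorm(50, 40, 10), rnorm(50, 60, 10)),  # 2 SD apart
      sex = sample(c("F", "M"), 100, replace = TRUE))
    cmp <- compare_demographics(co, continuous = "age")
    cmp$p_value[cmp$variable == "age"] < 0.01
  })
  expect_gte(mean(hits), 0.95)
})

test_that("zero-variance variables yield NaN with a warning, not an error", {
  co <- tibble::tibble(group = rep(c("control", "AMI"), each = 3),
                       age = rep(50, 6), sex = rep(c("F", "M"), 3))
  expect_warning(cmp <- compare_demographics(co, continuous = "age"),
                 "zero variance")
  expect_true(is.nan(cmp$p_value[cmp$variable == "age"]))
})

test_that("flow-by-CMR correlation table is long-form complete", {
  co <- simulate_cohort(seed = 60)
  co$ef_pct <- rnorm(31, 60, 5)
  tb <- correlate_flow_cmr(co, c("peak_systolic_base", "peak_systolic_mid"),
                           c("heart_rate", "ef_pct"))
  expect_equal(nrow(tb), 4)
  expect_true(all(abs(tb$rho) <= 1))
})
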