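test_that("percent-change transform is exact and monotone", {
  expect_equal(pct_change(0), 0)
  expect_equal(pct_change(-0.0173), (10^-0.0173 - 1) * 100)
  expect_equal(round(pct_change(-0.0173), 1), -3.9)
  expect_equal(pct_change(log10(0.96)), -4, tolerance = 1e-12)
  expect_equal(pct_change(5, "delta_r"), 5)
  b <- seq(-0.2, 0.2, by = 0.01)
  expect_true(all(diff(pct_change(b)) > 0))
})

test_that("robust fit agrees with OLS under clean Gaussian errors", {
  set.seed(31)
  n <- 2000
  d <- data.frame(x = rnorm(n), g = factor(sample(c("a", "b"), n, TRUE)))
  d$y <- 0.5 + 0.3 * d$x + 0.2 * (d$g == "b") + rnorm(n, 0, 0.4)
  rob <- fit_robust_model(y ~ x + g, d, outcome_type = "delta_r")
  ols <- lm(y ~ x + g, d)
  expect_equal(coef(rob), coef(ols), tolerance = 0.02)
  # ...but resists gross outliers that wreck OLS
  d$y[1:20] <- d$y[1:20] + 50
  rob2 <- fit_robust_model(y ~ x + g, d, outcome_type = "delta_r")
  ols2 <- lm(y ~ x + g, d)
  expect_lt(abs(coef(rob2)[["x"]] - 0.3), abs(coef(ols2)[["x"]] - 0.3) + 0.01)
  expect_equal(coef(rob2)[["x"]], 0.3, tolerance = 0.05)
})

test_that("robust fit refuses degenerate designs", {
  d <- data.frame(y = rnorm(30), x = rnorm(30))
  d$z <- d$x * 2 # collinear
  expect_error(fit_robust_model(y ~ x + z, d, "delta_r"), "rank-deficient")
  expect_error(fit_robust_model(y ~ x, d[1:8, ], "delta_r"), "too few")
})

test_that("association models return tertile effects on the right scale", {
  sim <- simulate_cohort(sim_config(seed = 14, n_per_cohort = 250))
  ana <- make_truth_analysis(sim)
  fit <- tl_assoc(ana, outcome = "tl4", exposure = "screen", model = "M3")
  expect_s3_class(fit, "tl_assoc")
  expect_equal(fit$effects$tertile, c("middle", "high"))
  expect_equal(fit$effects$pct_change,
               (10^fit$effects$beta - 1) * 100, tolerance = 1e-12)
  expect_true(all(fit$effects$ci_low <= fit$effects$pct_change &
                    fit$effects$pct_change <= fit$effects$ci_high))
  # delta-R outcome reports the coefficient itself
  fit2 <- tl_assoc(ana, outcome = "delta_r", exposure = "screen",
                   model = "M4")
  expect_equal(fit2$effects$pct_change, fit2$effects$beta)
  expect_lt(fit2$n, fit$n) # complete cases: tracking subset is smaller
  # model ladder contracts
  expect_error(tl_assoc(ana, outcome = "tl4", model = "M4"), "Model 4")
  expect_error(tl_assoc(ana, outcome = "tl4", model = "M9"), "unknown")
})

test_that("fitted-model methods delegate coherently", {
  sim <- simulate_cohort(small_config(seed = 15, n = 150))
  ana <- make_truth_analysis(sim)
  fit <- tl_assoc(ana, outcome = "tl4", exposure = "screen", model = "M2")
  expect_named(coef(fit)[1], "(Intercept)")
  ci <- confint(fit)
  expect_equal(unname(ci[, 2] - ci[, 1] > 0), rep(TRUE, nrow(ci)))
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(length(predict(fit)), fit$n)
  expect_output(print(fit), "Association model M2")
  expect_output(print(summary(fit)), "M-estimation")
})

test_that("heterogeneity matches the hand-computed worked example", {
  h <- heterogeneity(c(0, 1), c(0.5, 0.5))
  # weights 4 and 4, pooled 0.5, Q = 4*0.25 + 4*0.25 = 2, I2 = 50%
  expect_equal(h$beta_pooled, 0.5)
  expect_equal(h$Q, 2)
  expect_equal(h$df, 1L)
  expect_equal(h$i_squared, 50)
  expect_false(h$pool_with_cohort_covariate) # rule is strictly below 50%
  h0 <- heterogeneity(c(0.3, 0.3, 0.3), c(0.2, 0.3, 0.4))
  expect_equal(h0$Q, 0, tolerance = 1e-12)
  expect_equal(h0$i_squared, 0)
  expect_true(h0$pool_with_cohort_covariate)
  expect_error(heterogeneity(0.5, 0.2), "at least 2")
  expect_error(heterogeneity(c(0, 1), c(0.5, 0)), "positive")
})

test_that("heterogeneity agrees with a fixed-effect meta-analysis oracle", {
  skip_if_not_installed("metafor")
  set.seed(19)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    b <- rnorm(k, 0.2, 0.3)
    se <- runif(k, 0.1, 0.5)
    h <- heterogeneity(b, se)
    m <- metafor::rma(yi = b, sei = se, method = "FE")
    expect_equal(h$beta_pooled, as.numeric(m$beta), tolerance = 1e-8)
    expect_equal(h$Q, m$QE, tolerance = 1e-8)
    expect_equal(h$i_squared, m$I2, tolerance = 1e-6)
  }
})

test_that("per-cohort pooling runs and flags low heterogeneity", {
  sim <- simulate_cohort(sim_config(seed = 22, n_per_cohort = 250))
  ana <- make_truth_analysis(sim)
  het <- cohort_heterogeneity(ana, outcome = "tl4", exposure = "screen",
                              model = "M3")
  expect_s3_class(het, "tl_het")
  expect_equal(het$df, 2L)
  expect_true(het$i_squared >= 0 && het$i_squared <= 100)
  expect_length(attr(het, "fits"), 3L)
})

test_that("covariate selection keeps confounders and drops noise", {
  reps <- 20
  kept_conf <- kept_noise <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(sim_config(seed = 500 + r, n_per_cohort = 250))
    ana <- make_truth_analysis(sim)
    ana$pure_noise <- rnorm(nrow(ana))
    sel <- select_covariates(ana, outcome = "tl4", exposure = "screen",
                             candidates = c("upf_g", "pure_noise", "age4"),
                             forced = "cohort")
    kept_conf[r] <- "upf_g" %in% sel$selected
    kept_noise[r] <- "pure_noise" %in% sel$selected
  }
  expect_true(all(kept_conf)) # planted confounder always retained
  expect_gte(mean(!kept_noise), 0.9) # independent covariate excluded
})

test_that("covariate selection contracts: empty input, audit trail", {
  sim <- simulate_cohort(small_config(seed = 33, n = 120))
  ana <- make_truth_analysis(sim)
  empty <- select_covariates(ana, outcome = "tl4", exposure = "screen",
                             candidates = character(0))
  expect_identical(empty$selected, character(0))
  expect_equal(nrow(empty$trail), 0L)
  sel <- select_covariates(ana, outcome = "tl4", exposure = "screen",
                           candidates = c("upf_g", "sex"))
  expect_true(all(sel$trail$phase %in% c("bivariate", "backward", "forward")))
  expect_true(all(sel$trail$decision %in% c("keep", "drop", "add")))
  expect_gte(nrow(sel$trail), 2L)
})

test_that("descriptive tables choose tests by type and flag degeneracies", {
  set.seed(44)
  n <- 300
  g <- factor(rep(c("low", "middle", "high"), each = n / 3),
              levels = c("low", "middle", "high"))
  d <- data.frame(normal_var = rnorm(n, 10, 2),
                  skewed_var = rlnorm(n, 0, 1),
                  const_var = rep(1, n),
                  cat_var = factor(sample(c("x", "y"), n, TRUE)),
                  extreme_cat = factor(rep(c("a", "b", "b"), each = n / 3)))
  tab <- describe_by_tertile(d, g)
  expect_equal(tab$test[tab$variable == "normal_var"], "ANOVA")
  expect_equal(tab$test[tab$variable == "skewed_var"], "Kruskal-Wallis")
  expect_equal(tab$flag[tab$variable == "const_var"], "constant")
  expect_equal(tab$test[tab$variable == "cat_var"], "Chi-square")
  # all mass differences across groups: chi-square p near 0
  expect_lt(tab$p_value[tab$variable == "extreme_cat"], 1e-10)
  expect_error(describe_by_tertile(d, factor(rep("one", n))), "2 groups")
})

test_that("null descriptive comparisons do not systematically reject", {
  set.seed(55)
  reps <- 40
  p <- numeric(reps)
  g <- factor(rep(c("low", "middle", "high"), each = 50))
  for (r in seq_len(reps)) {
    d <- data.frame(v = rnorm(150))
    p[r] <- describe_by_tertile(d, g, vars = "v")$p_value
  }
  expect_lt(mean(p < 0.05), 0.2)
  expect_gt(mean(p), 0.3)
})

test_that("sensitivity suite refits all variants and flags small subgroups", {
  sim <- simulate_cohort(sim_config(seed = 66, n_per_cohort = 220))
  ana <- make_truth_analysis(sim)
  sens <- sensitivity_suite(ana, outcome = "tl4", exposure = "screen",
                            model = "M3")
  expect_setequal(unique(sens$variant),
                  c("main", "add_other_sb", "add_rmed", "add_bmi",
                    "add_season", "add_pa", "add_mother", "boys_only",
                    "girls_only", "exclude_preterm", "sex_interaction"))
  expect_true(all(is.na(sens$interaction_p[sens$variant != "sex_interaction"])))
  expect_true(all(!is.na(sens$interaction_p[sens$variant == "sex_interaction"])))
  # a covariate orthogonal to the exposure barely moves the estimate
  main <- sens$pct_change[sens$variant == "main" & sens$tertile == "high"]
  ana$orthogonal <- rnorm(nrow(ana))
  alt <- tl_assoc(ana, outcome = "tl4", exposure = "screen", model = "M3",
                  extra = "orthogonal")
  expect_equal(alt$effects$pct_change[alt$effects$tertile == "high"], main,
               tolerance = 0.25)
  # subgroup too small to fit is skipped with a flag
  tiny <- ana[1:40, ]
  sens2 <- sensitivity_suite(tiny, outcome = "tl4", exposure = "screen",
                             model = "M3",
                             variants = list(boys = list(
                               subset_expr = quote(sex == "male"))))
  expect_match(sens2$flag[1], "skipped")
})
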