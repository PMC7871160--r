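# Post-processing: effect-level prevalences, ratios, standardization,
# heterogeneity diagnostics.

test_that("effect prevalences match per-draw transform and enumeration", {
  g <- tiny_grid()
  spec <- apc_model_spec("apc")
  set.seed(99)
  m <- zero_draws(100, spec, g)
  m[, "delta"] <- rnorm(100, qlogis(0.3), 0.2)
  acols <- sprintf("alpha[%d]", 1:3)
  m[, acols] <- matrix(rnorm(300, 0, 0.3), 100, 3)
  m[, acols] <- m[, acols] - rowMeans(m[, acols])
  fit <- fake_fit(m, tiny_table(), g, spec)

  es <- effect_prevalence(fit, "age")
  # brute-force oracle over the 100 draws
  for (i in 1:3) {
    p <- plogis(m[, "delta"] + m[, acols[i]])
    expect_equal(es$estimate[i], mean(p))
    expect_equal(es$lower95[i], unname(quantile(p, 0.025)))
    expect_equal(es$upper95[i], unname(quantile(p, 0.975)))
  }
  expect_true(all(es$lower95 <= es$estimate & es$estimate <= es$upper95))
  expect_equal(es$level, c("20-24", "25-29", "30-34"))
})

test_that("degenerate and symmetric draw sets give the expected summaries", {
  g <- tiny_grid()
  spec <- apc_model_spec("apc")
  # constant draws: point mass, zero-width interval
  m <- zero_draws(50, spec, g)
  m[, "delta"] <- qlogis(0.3)
  fit <- fake_fit(m, tiny_table(), g, spec)
  es <- effect_prevalence(fit, "age")
  expect_equal(es$estimate, rep(0.3, 3), tolerance = 1e-12)
  expect_equal(es$upper95 - es$lower95, rep(0, 3))
  # delta = 0 with effects +/- c: estimates symmetric about 0.5
  m2 <- zero_draws(50, spec, g)
  m2[, "beta[1]"] <- 0.7
  m2[, "beta[2]"] <- -0.7
  fit2 <- fake_fit(m2, tiny_table(), g, spec)
  es2 <- effect_prevalence(fit2, "period")
  expect_equal(es2$estimate[1] + es2$estimate[2], 1, tolerance = 1e-12)
  # axis excluded from the model is refused
  spec_a <- apc_model_spec("a")
  fit_a <- fake_fit(zero_draws(50, spec_a, g), tiny_table(), g, spec_a)
  expect_error(effect_prevalence(fit_a, "cohort"), "not part of this model")
})

test_that("prevalence ratios divide estimates level by level", {
  mk <- function(est) {
    df <- data.frame(axis = "age", level = c("20-24", "25-29"),
                     estimate = est, lower95 = est - 0.01,
                     upper95 = est + 0.01, stringsAsFactors = FALSE)
    class(df) <- c("apc_effect", "data.frame")
    df
  }
  # a series against itself is identically 1
  s <- mk(c(0.31, 0.27))
  expect_equal(prevalence_ratio(s, s)$ratio, c(1, 1))
  # crude rates of the youngest men in 2004: 49.7% vs 44.8%
  r <- prevalence_ratio(mk(c(0.497, 0.2)), mk(c(0.448, 0.2)))
  expect_equal(r$ratio[1], 0.497 / 0.448)
  expect_equal(round(r$ratio[1], 3), 1.109)
  # common rescaling cancels
  sc <- prevalence_ratio(mk(0.9 * c(0.497, 0.2)), mk(0.9 * c(0.448, 0.2)))
  expect_equal(sc$ratio, r$ratio)
  # level mismatch and zero denominators are errors
  other <- mk(c(0.3, 0.4)); other$level <- c("30-34", "35-39")
  expect_error(prevalence_ratio(s, other), "same axis and levels")
  zero <- mk(c(0, 0.2))
  expect_error(prevalence_ratio(s, zero), "non-positive")
})

test_that("draw-wise ratios agree with enumeration over paired draws", {
  g <- tiny_grid()
  spec <- apc_model_spec("apc")
  set.seed(4)
  mknoise <- function() {
    m <- zero_draws(60, spec, g)
    m[, "delta"] <- rnorm(60, -0.5, 0.1)
    m
  }
  m1 <- mknoise(); m2 <- mknoise()
  f1 <- fake_fit(m1, tiny_table(), g, spec)
  f2 <- fake_fit(m2, tiny_table(), g, spec)
  r <- prevalence_ratio(f1, f2, axis = "age", type = "draws")
  oracle <- plogis(m1[, "delta"]) / plogis(m2[, "delta"])
  expect_equal(r$ratio, rep(mean(oracle), 3))
  expect_equal(r$lower95, rep(unname(quantile(oracle, 0.025)), 3))
  expect_error(prevalence_ratio(mknoise(), mknoise(), type = "draws"),
               "apc_fit")
})

test_that("direct age standardization is a normalized weighted mean", {
  # worked example: 0.5*0.1 + 0.3*0.2 + 0.2*0.4 = 0.19
  expect_equal(age_standardize(c(0.1, 0.2, 0.4),
                               standard_population(c(0.5, 0.3, 0.2))),
               0.19)
  # uniform prevalence is returned for any weights
  w <- standard_population(c(3, 1, 7))
  expect_equal(age_standardize(rep(0.23, 3), w), 0.23)
  # all weight on one group picks that group
  expect_equal(age_standardize(c(0.1, 0.2, 0.4),
                               standard_population(c(0, 0, 1))), 0.4)
  # linear in prevalences, invariant to weight rescaling
  p1 <- c(0.1, 0.3, 0.2); p2 <- c(0.05, 0.1, 0.4)
  expect_equal(age_standardize(0.3 * p1 + 0.7 * p2, w),
               0.3 * age_standardize(p1, w) + 0.7 * age_standardize(p2, w))
  expect_equal(age_standardize(p1, standard_population(c(30, 10, 70))),
               age_standardize(p1, w))
  # matrix input standardizes each column
  m <- cbind(p1, p2)
  expect_equal(age_standardize(m, w),
               c(age_standardize(p1, w), age_standardize(p2, w)))
  # errors
  expect_error(age_standardize(c(0.1, 0.2), w), "age groups")
  expect_error(standard_population(c(-1, 2)), "non-negative")
  expect_error(standard_population(c(0, 0)), "positive sum")
})

test_that("heterogeneity summaries expose structured residuals", {
  g <- tiny_grid()
  spec <- apc_model_spec("apc")
  # zero-variance z draws: all summaries zero
  fit0 <- fake_fit(zero_draws(30, spec, g), tiny_table(), g, spec)
  h0 <- heterogeneity_summary(fit0)
  expect_equal(h0$z_mean, matrix(0, 3, 2), ignore_attr = TRUE)
  expect_equal(h0$overall_sd, 0)
  # heterogeneity excluded -> informative error
  spec_no <- apc_model_spec("apc", include_heterogeneity = FALSE)
  fit_no <- fake_fit(zero_draws(30, spec_no, g), tiny_table(), g, spec_no)
  expect_error(heterogeneity_summary(fit_no), "without a heterogeneity")
})

test_that("omitting a real period effect leaves period-structured heterogeneity", {
  # generate data whose period effect declines, then fit the age-only
  # model: the unmodelled decline must surface as a decreasing trend in
  # the per-period means of z, and the APC fit must show less structure
  g <- smoking_survey_grid()
  tr <- simulate_truth(g, scenario = "age_period", seed = 31)
  tab <- simulate_prevalence_table(tr)
  fit_a <- quick_fit(tab, model = "a", iter = 400, seed = 31)
  fit_apc <- quick_fit(tab, model = "apc", iter = 400, seed = 31)
  h_a <- heterogeneity_summary(fit_a)
  h_apc <- heterogeneity_summary(fit_apc)
  rho <- cor(seq_len(g$J), h_a$by_period$mean, method = "spearman")
  expect_lt(rho, -0.8)  # monotone decreasing absorption of the trend
  # the well-specified model leaves less structure in z
  expect_gt(h_a$overall_sd, h_apc$overall_sd)
  expect_gt(diff(range(h_a$by_period$mean)),
            diff(range(h_apc$by_period$mean)))
})
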