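# MCMC sampling, convergence diagnostics and DIC.

test_that("single-cell intercept posterior matches 1-D quadrature", {
  y <- 300; n <- 1000
  tab <- prevalence_table(20, 2004, matrix(y), matrix(n), "cell")
  spec <- apc_model_spec(include_period = FALSE, include_cohort = FALSE,
                         include_heterogeneity = FALSE)
  fit <- apc_fit(tab, spec = spec, chains = 2, iter = 2000, warmup = 1000,
                 adapt = 500, seed = 42)
  d <- fit$draws[, "delta"]

  # exact posterior by numerical quadrature on the log-odds scale
  post <- function(x) dbinom(y, n, plogis(x)) * dnorm(x, 0, 10)
  Z <- integrate(post, -15, 15, rel.tol = 1e-12)$value
  quad_mean <- integrate(function(x) x * post(x), -15, 15,
                         rel.tol = 1e-12)$value / Z
  mcse <- sd(d) / sqrt(coda::effectiveSize(coda::mcmc(d)))
  expect_lt(abs(mean(d) - quad_mean), 3 * mcse)

  # DIC against the same quadrature
  res <- dic(fit)
  dev_fun <- function(x) -2 * dbinom(y, n, plogis(x), log = TRUE)
  dbar_q <- integrate(function(x) dev_fun(x) * post(x), -15, 15,
                      rel.tol = 1e-12)$value / Z
  phat_q <- integrate(function(x) plogis(x) * post(x), -15, 15,
                      rel.tol = 1e-12)$value / Z
  dic_q <- 2 * dbar_q - (-2 * dbinom(y, n, phat_q, log = TRUE))
  dev_draws <- dev_fun(d)
  mcse_dev <- sd(dev_draws) / sqrt(coda::effectiveSize(coda::mcmc(dev_draws)))
  expect_lt(abs(res$dic - dic_q), 4 * mcse_dev + 0.05)
})

test_that("sampling is reproducible and honours its seed", {
  tab <- tiny_table()
  f1 <- quick_fit(tab, iter = 200, seed = 5)
  f2 <- quick_fit(tab, iter = 200, seed = 5)
  f3 <- quick_fit(tab, iter = 200, seed = 6)
  expect_identical(f1$draws, f2$draws)
  expect_false(identical(f1$draws, f3$draws))
})

test_that("with huge denominators the fit concentrates on the truth", {
  g <- apc_grid(seq(20, 35, 5), seq(2004, 2010, 3))
  tr <- simulate_truth(g, scenario = "null", effect_scale = 0,
                       heterogeneity_sd = 0, denominators = 200000L,
                       seed = 3)
  tab <- simulate_prevalence_table(tr)
  fit <- apc_fit(tab, model = "a", chains = 2, iter = 500, warmup = 500,
                 adapt = 300, seed = 3)
  expect_lt(max(abs(fitted(fit) - 0.35)), 0.005)
})

test_that("every reported draw sits in the sum-to-zero gauge", {
  fit <- quick_fit(tiny_table(), iter = 200, seed = 8)
  g <- fit$grid
  for (eff in list(c("alpha", g$I), c("beta", g$J), c("gamma", g$K))) {
    cols <- sprintf("%s[%d]", eff[1], seq_len(as.integer(eff[2])))
    expect_lt(max(abs(rowSums(fit$draws[, cols]))), 1e-10)
  }
})

test_that("split R-hat separates mixed from unmixed chains", {
  set.seed(1)
  # chains drawn independently from one distribution: R-hat near 1
  expect_lt(split_rhat(list(rnorm(1000), rnorm(1000), rnorm(1000))), 1.05)
  # disjoint constant chains: R-hat far above any threshold
  expect_gt(split_rhat(list(rep(0, 100), rep(10, 100))), 1e6)
  # identical constants across chains: no disagreement, R-hat 1
  expect_equal(split_rhat(list(rep(2, 100), rep(2, 100))), 1)
  # a chain stuck away from the others is detected
  expect_gt(split_rhat(list(rnorm(500), rnorm(500) + 5)), 1.5)
  expect_error(split_rhat(list(rnorm(10))), "at least 2 chains")
  expect_error(split_rhat(list(1:3, 1:3)), ">= 4")
})

test_that("convergence checking reports offenders and needs 2 chains", {
  fit <- quick_fit(tiny_table(), model = "a", iter = 400, seed = 2)
  chk_inf <- check_convergence(fit, threshold = Inf)
  expect_true(chk_inf$pass)
  expect_length(chk_inf$offenders, 0)

  # an impossible threshold fails and names every finite-variance scalar
  chk0 <- check_convergence(fit, threshold = 0.5)
  expect_false(chk0$pass)
  expect_gt(length(chk0$offenders), 0)
  expect_true(all(chk0$offenders > 0.5))
  expect_equal(names(chk0$offenders)[1],
               names(which.max(chk0$rhat)))

  # subset restriction
  chk_sub <- check_convergence(fit, parameters = c("delta", "sigma_z"))
  expect_named(chk_sub$rhat, c("delta", "sigma_z"))
  expect_error(check_convergence(fit, parameters = "nope"), "unknown")

  f1 <- apc_fit(tiny_table(), model = "a", chains = 1, iter = 200,
                warmup = 200, adapt = 200, seed = 1)
  expect_error(check_convergence(f1), "at least 2 chains")
})

test_that("DIC obeys its identities and is zero-variance-consistent", {
  g <- tiny_grid()
  tab <- tiny_table()
  spec <- apc_model_spec("apc")
  # degenerate 'model': identical draws -> pd = 0, dic = dbar = dhat
  m <- zero_draws(40, spec, g)
  m[, "delta"] <- qlogis(0.35)
  f0 <- fake_fit(m, tab, g, spec)
  d0 <- dic(f0)
  expect_equal(d0$pd, 0, tolerance = 1e-8)
  expect_equal(d0$dic, d0$dbar, tolerance = 1e-8)
  expect_equal(d0$dbar, d0$dhat, tolerance = 1e-8)
  # identity on a real fit
  fit <- quick_fit(tab, iter = 300, seed = 4)
  d <- dic(fit)
  expect_equal(d$dic, d$dbar + d$pd, tolerance = 1e-12)
  expect_equal(d$pd, d$dbar - d$dhat, tolerance = 1e-12)
  expect_equal(d$dic, d$dhat + 2 * d$pd, tolerance = 1e-12)
  expect_gt(d$pd, 0)
})

test_that("dic_table ranks submodels and carries the model codes", {
  tab <- tiny_table()
  fits <- list(a = quick_fit(tab, "a", iter = 200, seed = 1),
               apc = quick_fit(tab, "apc", iter = 200, seed = 1))
  dt <- dic_table(fits)
  expect_equal(sort(dt$model), c("a", "apc"))
  expect_false(is.unsorted(dt$dic))
  expect_equal(dt$delta_dic[1], 0)
  expect_true(all(is.finite(dt$dic)))
})

test_that("fit methods expose coherent summaries", {
  tab <- tiny_table()
  fit <- quick_fit(tab, iter = 300, seed = 10)
  # fitted probabilities live in (0,1) and track the crude rates
  p <- fitted(fit)
  expect_true(all(p > 0 & p < 1))
  expect_lt(max(abs(p - observed_prevalence(tab))), 0.2)
  # coef returns centred posterior means
  cf <- coef(fit)
  expect_lt(abs(sum(cf[sprintf("alpha[%d]", 1:3)])), 1e-10)
  # residuals are standardized
  expect_equal(dim(residuals(fit)), dim(tab$smokers))
  # simulate returns valid tables with the same denominators
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  for (s in sims) {
    expect_s3_class(s, "prevalence_table")
    expect_identical(s$denominators, tab$denominators)
  }
  # summary prints without error and carries the DIC
  sm <- summary(fit)
  expect_s3_class(sm$dic, "apc_dic")
  expect_output(print(sm), "Model: apc")
  expect_output(print(fit), "binomial age-period-cohort")
})
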