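test_that("GEE matches an independent GEE implementation on a frozen fixture", {
  # reference values computed once with statsmodels GEE (Poisson family) on
  # the byte-identical table from gee_fixture(): default robust covariance
  # for the uncorrected sandwich, cov_type="bias_reduced" for the
  # Mancl-DeRouen corrected one
  tab <- gee_fixture()
  fx <- fit_gee(tab, covariates = c("x1", "x2"), corstr = "exchangeable",
                correction = "none")
  expect_equal(fx$coefficients$estimate,
               c(0.9302783753, 0.3048949481, 0.1670345505), tolerance = 1e-8)
  expect_equal(fx$coefficients$se,
               c(0.2478737501, 0.1457216405, 0.0468471703), tolerance = 1e-7)
  expect_equal(fx$alpha, 0.5294574955, tolerance = 1e-7)
  fmd <- fit_gee(tab, covariates = c("x1", "x2"), corstr = "exchangeable")
  expect_equal(fmd$coefficients$estimate, fx$coefficients$estimate,
               tolerance = 1e-10) # correction touches only the variance
  expect_equal(fmd$coefficients$se,
               c(0.3350234787, 0.2004495740, 0.0532910303), tolerance = 1e-7)
  fi <- fit_gee(tab, covariates = c("x1", "x2"), corstr = "independence",
                correction = "none")
  expect_equal(fi$coefficients$estimate,
               c(0.9224169738, 0.2957279684, 0.1633151676), tolerance = 1e-8)
  expect_equal(fi$coefficients$se,
               c(0.3015241681, 0.1712052406, 0.0532271294), tolerance = 1e-7)
})

test_that("independence GEE equals Poisson GLM with a cluster sandwich", {
  skip_if_not_installed("sandwich")
  tab <- gee_fixture()
  fit <- fit_gee(tab, covariates = c("x1", "x2"), corstr = "independence",
                 correction = "none")
  g <- glm(count ~ x1 + x2, poisson, data = tab)
  expect_equal(fit$coefficients$estimate, unname(coef(g)), tolerance = 1e-8)
  v <- sandwich::vcovCL(g, cluster = tab$cluster, type = "HC0", cadjust = FALSE)
  expect_equal(fit$coefficients$se, unname(sqrt(diag(v))), tolerance = 1e-6)
})

test_that("a constant outcome gives intercept log(c) and zero slopes", {
  tab <- data.frame(count = 7L, cluster = factor(rep(1:4, each = 10)),
                    x1 = rnorm(40))
  fit <- fit_gee(tab, covariates = "x1")
  expect_equal(fit$coefficients$estimate[1], log(7), tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate[2], 0, tolerance = 1e-8)
})

test_that("one observation per cluster reduces GEE to Poisson regression", {
  set.seed(55)
  d <- data.frame(count = rpois(30, 4), cluster = factor(1:30),
                  x1 = rnorm(30))
  fit <- fit_gee(d, covariates = "x1", corstr = "independence")
  g <- glm(count ~ x1, poisson, data = d)
  expect_equal(fit$coefficients$estimate, unname(coef(g)), tolerance = 1e-8)
})

test_that("estimates are invariant to row order of the analysis table", {
  set.seed(61)
  tab <- gee_fixture()
  perm <- sample(nrow(tab))
  for (cs in c("exchangeable", "independence")) {
    a <- fit_gee(tab, covariates = c("x1", "x2"), corstr = cs)
    b <- fit_gee(tab[perm, ], covariates = c("x1", "x2"), corstr = cs)
    expect_equal(a$coefficients$estimate, b$coefficients$estimate,
                 tolerance = 1e-9)
    expect_equal(a$coefficients$se, b$coefficients$se, tolerance = 1e-9)
  }
})

test_that("structural errors: single cluster, missing covariates, empty table", {
  tab <- gee_fixture()
  one <- tab; one$cluster <- factor("only")
  expect_error(fit_gee(one, covariates = "x1"), class = "pa_structural_error")
  expect_error(fit_gee(tab, covariates = "nope"), class = "pa_structural_error")
  expect_error(fit_gee(tab[0, ], covariates = "x1"),
               class = "pa_structural_error")
})

test_that("confidence bounds bracket the estimate and order is fixed", {
  s <- gen_study(fast_config(seed = 19))
  tab <- build_analysis_table(s$scans, s$contexts)
  bat <- run_model_battery(tab)
  expect_named(bat$fits, c("types_only", "l2_only", "types_plus_l2"))
  for (f in bat$fits) {
    expect_true(f$converged)
    expect_lte(f$n_clusters, f$n_obs)
    cf <- f$coefficients
    expect_true(all(cf$ci_low <= cf$estimate & cf$estimate <= cf$ci_high))
  }
  expect_setequal(bat$fits$types_only$coefficients$term,
                  c("(Intercept)", "n_types", "n_establishments_z", "cpat"))
  expect_setequal(bat$fits$types_plus_l2$coefficients$term,
                  c("(Intercept)", "n_types", "l2", "n_establishments_z",
                    "cpat"))
  res <- battery_results(bat)
  expect_equal(unique(res$model), c("types_only", "l2_only", "types_plus_l2"))
  expect_equal(bat$attenuation$b_types_alone,
               bat$fits$types_only$coefficients$estimate[2])
})

test_that("conclusions are insensitive to the working correlation choice", {
  # with cluster-level exposures the two working correlations weight
  # unbalanced parks differently, so coefficients agree approximately (on
  # the per-SD covariate scale) and the substantive calls agree exactly
  covs <- c("n_types_z", "l2_z", "n_establishments_z", "cpat_z")
  for (seed in c(23, 31)) {
    s <- gen_study(fast_config(seed = seed))
    tab <- build_analysis_table(s$scans, s$contexts)
    ex <- fit_gee(tab, covariates = covs, corstr = "exchangeable")
    ind <- fit_gee(tab, covariates = covs, corstr = "independence")
    expect_equal(ex$coefficients$estimate, ind$coefficients$estimate,
                 tolerance = 0.06)
    # no strongly significant result under one working correlation may look
    # clearly null under the other (borderline p ~ 0.05 flips are expected)
    clash <- (ex$coefficients$p < 0.01 & ind$coefficients$p > 0.1) |
      (ind$coefficients$p < 0.01 & ex$coefficients$p > 0.1)
    expect_false(any(clash))
  }
})

test_that("compare_measures matches the from-scratch Pearson formula", {
  x <- c(1, 2, 3.5, 7)
  expect_equal(compare_measures(x, x)$r, 1)
  expect_equal(compare_measures(x, -x)$r, -1)
  set.seed(77)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  got <- compare_measures(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  tstat <- r_hand * sqrt(18 / (1 - r_hand^2))
  expect_equal(got$p, 2 * pt(-abs(tstat), df = 18), tolerance = 1e-12)
  expect_error(compare_measures(a, rep(1, 20)), class = "pa_degenerate_error")
  expect_error(compare_measures(1:2, 1:2), class = "pa_structural_error")
})
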