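test_that("zero-noise flat profile yields an all-100 matrix", {
  cfg <- sim_config(noise_sd = 0, day_sd = 0,
                    type_profiles = c(default_type_profiles(),
                                      list(flat = rep(1, 24))))
  w <- gen_popularity("flat", cfg, seed = 1)
  expect_true(all(unclass(w) == 100L))
})

test_that("night-peaked bar profiles peak in the late evening", {
  cfg <- sim_config()
  for (seed in 1:5) {
    w <- gen_popularity("Bar", cfg, seed = seed)
    peak_hour <- as.integer(names(which.max(mean_daily(w))))
    expect_true(peak_hour >= 20 || peak_hour <= 1)
  }
  expect_error(gen_popularity("no-such-type", cfg),
               class = "pa_structural_error")
})

test_that("generated popularity obeys the Popular Times conventions", {
  cfg <- sim_config()
  for (seed in 1:10) {
    tp <- sample(names(cfg$type_weights), 1)
    w <- unclass(gen_popularity(tp, cfg, seed = seed))
    expect_equal(max(w), 100)
    expect_true(all(w >= 0 & w <= 100))
    expect_true(all(w == round(w)))
    # closed hours of the base shape stay closed
    closed <- which(cfg$type_profiles[[tp]] == 0)
    if (length(closed) > 0) expect_true(all(w[, closed] == 0))
  }
})

test_that("the same seed reproduces bit-identical draws and studies", {
  cfg <- sim_config()
  expect_identical(gen_popularity("Cafe", cfg, seed = 9),
                   gen_popularity("Cafe", cfg, seed = 9))
  s1 <- gen_study(fast_config(seed = 3))
  s2 <- gen_study(fast_config(seed = 3))
  expect_identical(s1$scans, s2$scans)
  expect_identical(s1$establishments, s2$establishments)
  expect_identical(s1$contexts, s2$contexts)
})

test_that("the same seed writes byte-identical study files", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  gen_study(fast_config(seed = 5), dir = d1)
  gen_study(fast_config(seed = 5), dir = d2)
  for (f in c("target_areas.geojson", "establishments.json", "cpat.csv",
              "scans.csv", "truth.json")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("an intercept-only truth gives the planted grand mean count", {
  cfg <- sim_config(true_beta = c(intercept = log(5), n_types = 0, l2 = 0,
                                  n_establishments_z = 0, cpat = 0),
                    random_intercept_sd = 0,
                    establishments_per_park = c(150L, 600L),
                    popularity_coverage = 0.1, seed = 29)
  s <- gen_study(cfg)
  n <- nrow(s$scans)
  expect_gt(n, 5000)
  se <- sqrt(5 / n)
  expect_lt(abs(mean(s$scans$count) - 5), 3 * se)
})

test_that("generated studies satisfy the domain invariants", {
  s <- gen_study(fast_config(seed = 43))
  expect_true(all(s$scans$count >= 0 & s$scans$count == round(s$scans$count)))
  expect_true(all(table(s$target_areas$park_id) >= 4 &
                  table(s$target_areas$park_id) <= 13))
  expect_true(all(s$cpat$overall >= 0 & s$cpat$overall <= 100))
  obs <- s$establishments[!vapply(s$establishments$weekly, is.null,
                                  logical(1)), ]
  frac <- nrow(obs) / nrow(s$establishments)
  expect_gt(frac, 0.05); expect_lt(frac, 0.2)
  expect_true(all(s$establishments$type %in%
                  names(default_type_weights)))
})

test_that("full coverage makes imputation a no-op", {
  cfg <- sim_config(popularity_coverage = 1,
                    establishments_per_park = c(30L, 60L), seed = 47)
  s <- gen_study(cfg)
  expect_true(all(!vapply(s$establishments$weekly, is.null, logical(1))))
  res <- impute_popularity(s$establishments)
  expect_equal(nrow(res$provenance), 0L)
  expect_identical(res$establishments, s$establishments)
})

test_that("the full pipeline closes over many random seeds", {
  cfg_base <- sim_config(establishments_per_park = c(80L, 200L),
                         popularity_coverage = 0.15)
  for (seed in 1:50) {
    cfg <- cfg_base; cfg$seed <- seed
    s <- gen_study(cfg)
    est <- s$establishments
    imp <- impute_popularity(est, policy = "lenient")
    ctx <- compute_park_contexts(imp$establishments, s$buffers, s$cpat)
    tab <- build_analysis_table(s$scans, ctx)
    fit <- fit_gee(tab, "types_plus_l2")
    expect_true(fit$converged)
  }
})

test_that("infeasible geometry is retried and then reported", {
  cfg <- sim_config(establishments_per_park = c(1L, 1L),
                    popularity_coverage = 0.01, max_retries = 3L, seed = 2)
  expect_error(gen_study(cfg), class = "pa_degenerate_error")
})

test_that("sim_config validates its fields", {
  expect_error(sim_config(popularity_coverage = 0), class = "pa_structural_error")
  expect_error(sim_config(popularity_coverage = 1.5), class = "pa_structural_error")
  expect_error(sim_config(target_areas_per_park = c(5, 2)),
               class = "pa_structural_error")
  expect_error(sim_config(true_beta = c(intercept = 1)),
               class = "pa_structural_error")
  expect_error(sim_config(n_parks = 1), class = "pa_structural_error")
})
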