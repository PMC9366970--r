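test_that("mean_daily averages each hour across the seven days", {
  v <- sample(0:100, 24, replace = TRUE)
  expect_equal(unname(mean_daily(weekly_from_daily(v))), as.numeric(v))
  expect_equal(unname(mean_daily(weekly_popularity(matrix(0L, 7, 24)))),
               rep(0, 24))
  # 4 days of 100 and 3 of 0 at hour 3 -> 400/7
  m <- matrix(0L, 7, 24)
  m[1:4, 4] <- 100L
  expect_equal(mean_daily(m)[["3"]], 400 / 7)
})

test_that("weekly popularity validation rejects malformed input", {
  expect_error(weekly_popularity(matrix(0, 6, 24)), class = "pa_structural_error")
  expect_error(weekly_popularity(matrix(0, 7, 23)), class = "pa_structural_error")
  expect_error(weekly_popularity(matrix(101, 7, 24)), class = "pa_structural_error")
  expect_error(weekly_popularity(matrix(-1, 7, 24)), class = "pa_structural_error")
  expect_error(weekly_popularity(matrix(0.5, 7, 24)), class = "pa_structural_error")
  expect_error(weekly_popularity(matrix(NA_real_, 7, 24)),
               class = "pa_structural_error")
})

test_that("activation_distribution pools and normalizes establishment profiles", {
  u <- activation_distribution(rep(3, 24))
  expect_equal(unname(u), rep(1 / 24, 24))
  # mirror-image establishments summing to a constant -> uniform
  a <- c(seq(0, 23), rep(0, 0))
  b <- 23 - a
  expect_equal(unname(activation_distribution(list(a, b))), rep(1 / 24, 24))
  # hand-computed two-establishment case
  d1 <- c(2, rep(0, 23))
  d2 <- c(0, 2, rep(0, 22))
  expect_equal(unname(activation_distribution(list(d1, d2))),
               c(0.5, 0.5, rep(0, 22)))
  expect_equal(sum(activation_distribution(runif(24))), 1)
})

test_that("all-zero popularity raises a degenerate-input error", {
  expect_error(activation_distribution(rep(0, 24)), class = "pa_degenerate_error")
  expect_error(activation_distribution(list(rep(0, 24), rep(0, 24))),
               class = "pa_degenerate_error")
  expect_error(activation_distribution(list()), class = "pa_structural_error")
  expect_error(activation_distribution(list(rep(-1, 24))),
               class = "pa_structural_error")
})

test_that("l2_norm attains its closed-form bounds and cases", {
  expect_equal(l2_norm(activation_distribution(rep(1, 24))), 1 / sqrt(24))
  expect_equal(l2_norm(activation_distribution(c(9, rep(0, 23)))), 1)
  two <- activation_distribution(c(5, 5, rep(0, 22)))
  expect_equal(l2_norm(two), 1 / sqrt(2))
  expect_error(l2_norm(rep(0.5, 24)), class = "pa_structural_error")
  expect_error(l2_norm(rep(1 / 23, 23)), class = "pa_structural_error")
})

test_that("l2_norm stays within [1/sqrt(24), 1] over random distributions", {
  set.seed(101)
  for (i in 1:10000) {
    p <- rexp(24)
    val <- l2_norm(activation_distribution(p))
    expect_true(val >= 1 / sqrt(24) - 1e-12 && val <= 1 + 1e-12)
  }
})

test_that("l2 is scale invariant and permutation invariant", {
  set.seed(7)
  for (i in 1:50) {
    dailies <- replicate(4, runif(24, 0, 50), simplify = FALSE)
    base <- park_l2(dailies)
    cc <- runif(1, 0.01, 100)
    scaled <- park_l2(lapply(dailies, function(d) d * cc))
    expect_equal(scaled, base, tolerance = 1e-12)
    perm <- sample(24)
    expect_equal(park_l2(lapply(dailies, function(d) d[perm])), base,
                 tolerance = 1e-12)
  }
})

test_that("transferring mass toward the busier hour never decreases the L2", {
  set.seed(11)
  for (i in 1:200) {
    p <- as.numeric(activation_distribution(rexp(24)))
    ij <- sample(24, 2)
    lo <- ij[which.min(p[ij])]
    hi <- ij[which.max(p[ij])]
    eps <- runif(1, 0, p[lo])
    q <- p
    q[lo] <- q[lo] - eps
    q[hi] <- q[hi] + eps
    expect_gte(l2_norm(q / sum(q)), l2_norm(p) - 1e-12)
  }
})

test_that("l2 matches the loop-based recomputation from raw weekly matrices", {
  set.seed(23)
  for (i in 1:50) {
    ws <- replicate(sample(1:8, 1), random_weekly(), simplify = FALSE)
    dailies <- lapply(ws, mean_daily)
    expect_equal(park_l2(dailies), l2_loop_oracle(ws), tolerance = 1e-12)
  }
})

test_that("windowed L2 restricts and renormalizes over the window", {
  set.seed(5)
  dailies <- replicate(3, runif(24, 0, 30), simplify = FALSE)
  expect_equal(l2_norm_windowed(dailies, 0, 23),
               park_l2(dailies), tolerance = 1e-12)
  expect_equal(l2_norm_windowed(list(rep(4, 24)), 9, 19), 1 / sqrt(11))
  # all mass outside the window -> degenerate
  night <- c(rep(5, 9), rep(0, 11), rep(5, 4))
  expect_error(l2_norm_windowed(list(night), 9, 19),
               class = "pa_degenerate_error")
  expect_error(l2_norm_windowed(dailies, 12, 9), class = "pa_structural_error")
  expect_error(l2_norm_windowed(dailies, -1, 5), class = "pa_structural_error")
})

test_that("non-renormalized windowed L2 keeps the full-day denominator", {
  dailies <- list(c(rep(10, 12), rep(0, 12)))
  hourly <- rep(10, 12)
  expected <- sqrt(sum((hourly / 120)^2)) # mass 10/120 in each of 12 hours
  expect_equal(l2_norm_windowed(dailies, 0, 11, renormalize = FALSE), expected)
  # renormalized version of the same window is uniform over 12 hours
  expect_equal(l2_norm_windowed(dailies, 0, 11), 1 / sqrt(12))
})
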