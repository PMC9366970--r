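# Shared fixtures and independent oracles. Oracles are deliberately written
# as naive loops / closed forms, independent of the package's vectorized
# implementations.

# a weekly matrix whose every row is the same 24-vector
weekly_from_daily <- function(daily) {
  weekly_popularity(matrix(rep(round(daily), each = 7), 7, 24))
}

random_weekly <- function() {
  weekly_popularity(matrix(sample(0:100, 168, replace = TRUE), 7, 24))
}

# naive loop-based recomputation of the buffer L2 norm straight from raw
# weekly matrices: mean over days per hour, pool establishments, normalize
# over the day, square, sum, root
l2_loop_oracle <- function(weeklies) {
  dailies <- list()
  for (i in seq_along(weeklies)) {
    w <- unclass(weeklies[[i]])
    v <- numeric(24)
    for (h in 1:24) {
      s <- 0
      for (d in 1:7) s <- s + w[d, h]
      v[h] <- s / 7
    }
    dailies[[i]] <- v
  }
  tot <- 0
  for (v in dailies) for (h in 1:24) tot <- tot + v[h]
  ssq <- 0
  for (h in 1:24) {
    sh <- 0
    for (v in dailies) sh <- sh + v[h]
    ssq <- ssq + (sh / tot)^2
  }
  sqrt(ssq)
}

# exhaustive nearest same-type search with lexicographic id tie-break
impute_oracle <- function(targets, refs) {
  out <- character(nrow(targets))
  for (i in seq_len(nrow(targets))) {
    best_d <- Inf
    best_id <- NA_character_
    for (j in seq_len(nrow(refs))) {
      if (refs$type[[j]] != targets$type[[i]]) next
      d <- sqrt((targets$x[[i]] - refs$x[[j]])^2 +
                (targets$y[[i]] - refs$y[[j]])^2)
      if (d < best_d || (d == best_d && refs$id[[j]] < best_id)) {
        best_d <- d
        best_id <- refs$id[[j]]
      }
    }
    out[[i]] <- best_id
  }
  out
}

# area of the union of two equal-radius discs (closed-form lens)
two_disc_union_area <- function(d, r) {
  if (d >= 2 * r) return(2 * pi * r^2)
  lens <- 2 * r^2 * acos(d / (2 * r)) - (d / 2) * sqrt(4 * r^2 - d^2)
  2 * pi * r^2 - lens
}

# random establishment table with types and coordinates; frac of rows carry
# weekly popularity
random_establishments <- function(n, types = LETTERS[1:5], frac = 0.5,
                                  extent = 1000) {
  weekly <- lapply(seq_len(n), function(i) {
    if (i <= round(n * frac)) unclass(random_weekly()) else NULL
  })
  establishments(
    id = sprintf("e%04d", sample.int(9999, n)),
    x = runif(n, 0, extent), y = runif(n, 0, extent),
    raw_category = "restaurant",
    type = sample(types, n, replace = TRUE),
    weekly = weekly
  )
}

# deterministic small clustered-count fixture; the statsmodels GEE numbers
# frozen in test-modeling.R were computed from exactly this table
gee_fixture <- function() {
  set.seed(42)
  sizes <- sample(5:12, 8, replace = TRUE)
  cl <- rep(seq_along(sizes), sizes)
  x1 <- rep(round(rnorm(8), 3), sizes)
  x2 <- round(runif(sum(sizes), -1, 1), 3)
  u <- rep(round(rnorm(8, 0, 0.4), 3), sizes)
  y <- rpois(sum(sizes), exp(1 + 0.3 * x1 - 0.2 * x2 + u))
  data.frame(count = y, cluster = factor(cl), x1 = x1, x2 = x2)
}

# compact simulation config for fast pipeline-level tests (smaller
# establishment listings; same park/scan design)
fast_config <- function(seed = 1L, ...) {
  sim_config(establishments_per_park = c(150L, 600L),
             popularity_coverage = 0.1, seed = seed, ...)
}
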