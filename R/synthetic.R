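# Synthetic study generator: establishments with category-dependent weekly
# popularity profiles, park layouts with jittered point target areas, CPAT
# scores, and scan counts drawn from a log-linear Poisson model with a
# park-level normal random intercept (so the GEE's cluster correction is
# actually exercised).

circular_bump <- function(center, width, floor = 0) {
  h <- 0:23
  d <- pmin(abs(h - center), 24 - abs(h - center))
  pmax(exp(-0.5 * (d / width)^2), floor)
}

default_type_profiles <- function() {
  prof <- list(
    "Restaurant" = circular_bump(12.5, 2) + circular_bump(19, 2.5),
    "Cafe" = circular_bump(8.5, 2.5) + 0.3 * circular_bump(14, 3),
    "Bar" = circular_bump(22, 2.5),
    "Grocery" = 0.25 + circular_bump(17.5, 3.5),
    "Retail/services" = circular_bump(14, 4),
    "Health/medical" = circular_bump(11, 3.5),
    "Education" = circular_bump(10, 3),
    "Finance" = circular_bump(12, 3),
    "Lodging" = 0.6 + 0.4 * circular_bump(20, 3),
    "Transit" = circular_bump(8.5, 1.5) + circular_bump(17.5, 1.5) + 0.2,
    "Recreation/fitness" = circular_bump(7, 1.5) + circular_bump(18.5, 2.5),
    "Culture" = circular_bump(14, 3.5),
    "Religious" = circular_bump(11, 2),
    "Government/civic" = circular_bump(11, 3),
    "Other" = circular_bump(13, 6)
  )
  lapply(prof, function(v) {
    v <- v / max(v)
    v[v < 0.02] <- 0 # closed hours
    v
  })
}

# heavily skewed, as real category frequencies are: a handful of ubiquitous
# types and a long tail of rare ones, so the number of distinct types in a
# buffer varies across parks even for exhaustive listings
default_type_weights <- c(
  "Restaurant" = 0.26, "Retail/services" = 0.28, "Grocery" = 0.13,
  "Cafe" = 0.09, "Health/medical" = 0.07, "Bar" = 0.05, "Other" = 0.0445,
  "Finance" = 0.025, "Education" = 0.02, "Recreation/fitness" = 0.015,
  "Transit" = 0.008, "Religious" = 0.004, "Culture" = 0.002,
  "Government/civic" = 0.001, "Lodging" = 0.0005
)

# raw category synonyms per type, so the generated data exercises the
# raw-category -> type mapping
default_raw_synonyms <- function() {
  cmap <- default_category_map()
  split(names(cmap$entries), unname(cmap$entries))
}

#' Simulation configuration
#'
#' Study-design defaults mirror the magnitudes of the observational design
#' the generator emulates: 20 parks with 4--13 point target areas each,
#' 250 m buffers, a popularity-observation coverage of 6% of an exhaustive
#' (NETS-like) establishment listing of 300--3000 establishments per park
#' vicinity, 8 observation visits per park with 2--3 hour-long periods and
#' 1--4 completed rounds per period (about 10,000 scans overall), and scan
#' counts with a grand mean near 5 persons. Planted coefficients default to
#' small paper-scale associations; `effect_scale = "standardized"` plants
#' them per standard deviation of each park-level covariate instead of on
#' the raw covariate scales.
#'
#' @param n_parks number of parks (default 20).
#' @param target_areas_per_park inclusive integer range (default `c(4, 13)`).
#' @param buffer_radius_m buffer radius in meters (default 250).
#' @param establishments_per_park inclusive range of total establishments
#'   scattered around each park (log-uniform; default `c(300, 3000)`).
#' @param popularity_coverage fraction of establishments with observed
#'   weekly popularity (default 0.06).
#' @param type_profiles named list of 24-hour base shapes per type (max 1).
#' @param type_weights sampling weights over types.
#' @param noise_sd lognormal cell-noise SD of popularity (default 0.25).
#' @param day_sd lognormal day-to-day scale SD (default 0.15).
#' @param true_beta named vector: intercept, n_types, l2,
#'   n_establishments_z, cpat.
#' @param effect_scale `"raw"` (covariates enter the log-mean on their
#'   natural scales, establishment count Z-scored) or `"standardized"` (all
#'   four covariates Z-scored across parks).
#' @param random_intercept_sd park-level log-scale random-intercept SD
#'   (default 0.3).
#' @param visits_per_park,periods_per_visit,rounds_weights scan-schedule
#'   knobs: number of visits, inclusive range of periods per visit, and
#'   sampling weights for 1--4 completed rounds per period.
#' @param cpat_mean,cpat_sd CPAT domain score distribution (clipped to
#'   0--100).
#' @param seed integer seed; all randomness flows from it.
#' @param max_retries per-park regeneration cap when a buffer ends up with
#'   no popularity-carrying establishment.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_parks = 20L,
                       target_areas_per_park = c(4L, 13L),
                       buffer_radius_m = 250,
                       establishments_per_park = c(300L, 3000L),
                       popularity_coverage = 0.06,
                       type_profiles = default_type_profiles(),
                       type_weights = default_type_weights,
                       noise_sd = 0.25,
                       day_sd = 0.15,
                       true_beta = c(intercept = 0.86, n_types = 0.029,
                                     l2 = 1.073, n_establishments_z = 0.128,
                                     cpat = 0.004),
                       effect_scale = c("raw", "standardized"),
                       random_intercept_sd = 0.3,
                       visits_per_park = 8L,
                       periods_per_visit = c(2L, 3L),
                       rounds_weights = c(0.05, 0.10, 0.25, 0.60),
                       cpat_mean = 55, cpat_sd = 12,
                       seed = 1L,
                       max_retries = 25L) {
  effect_scale <- match.arg(effect_scale)
  if (n_parks < 2L) pa_stop_structural("need at least two parks")
  chk_range <- function(r, nm) {
    if (length(r) != 2L || any(r < 1) || r[1L] > r[2L]) {
      pa_stop_structural(sprintf("'%s' must be a non-empty inclusive range", nm))
    }
  }
  chk_range(target_areas_per_park, "target_areas_per_park")
  chk_range(establishments_per_park, "establishments_per_park")
  chk_range(periods_per_visit, "periods_per_visit")
  if (popularity_coverage <= 0 || popularity_coverage > 1) {
    pa_stop_structural("popularity_coverage must lie in (0, 1]")
  }
  if (!all(names(type_weights) %in% names(type_profiles))) {
    pa_stop_structural("every weighted type needs a profile")
  }
  ok <- vapply(type_profiles, function(v) {
    is.numeric(v) && length(v) == 24L && all(is.finite(v)) && all(v >= 0) &&
      max(v) > 0
  }, logical(1))
  if (!all(ok)) pa_stop_structural("type profiles must be non-negative 24-vectors with positive max")
  need_beta <- c("intercept", "n_types", "l2", "n_establishments_z", "cpat")
  if (!all(need_beta %in% names(true_beta))) {
    pa_stop_structural(sprintf("true_beta needs components: %s",
                               paste(need_beta, collapse = ", ")))
  }
  if (length(rounds_weights) != 4L || any(rounds_weights < 0) ||
      sum(rounds_weights) <= 0) {
    pa_stop_structural("rounds_weights must be four non-negative weights")
  }
  structure(list(
    n_parks = as.integer(n_parks),
    target_areas_per_park = as.integer(target_areas_per_park),
    buffer_radius_m = buffer_radius_m,
    establishments_per_park = as.integer(establishments_per_park),
    popularity_coverage = popularity_coverage,
    type_profiles = type_profiles,
    type_weights = type_weights,
    noise_sd = noise_sd, day_sd = day_sd,
    true_beta = true_beta[need_beta],
    effect_scale = effect_scale,
    random_intercept_sd = random_intercept_sd,
    visits_per_park = as.integer(visits_per_park),
    periods_per_visit = as.integer(periods_per_visit),
    rounds_weights = rounds_weights,
    cpat_mean = cpat_mean, cpat_sd = cpat_sd,
    seed = as.integer(seed),
    max_retries = as.integer(max_retries)
  ), class = "sim_config")
}

#' Generate one establishment's weekly popularity matrix
#'
#' Scales the type's 24-hour base shape per day, applies multiplicative
#' lognormal noise, clips to `[0, 100]`, and rescales so the busiest hour of
#' the week is exactly 100 (the Popular Times convention). Hours where the
#' base shape is zero stay zero (closed).
#'
#' @param type_name a type with a profile in `config`.
#' @param config a [sim_config()].
#' @param seed optional seed for a standalone reproducible draw; inside
#'   [gen_study()] the global stream is used.
#' @return a [weekly_popularity()] matrix.
#' @export
gen_popularity <- function(type_name, config = sim_config(), seed = NULL) {
  shape <- config$type_profiles[[type_name]]
  if (is.null(shape)) {
    pa_stop_structural(sprintf("no popularity profile for type '%s'", type_name))
  }
  if (!is.null(seed)) set.seed(seed)
  day_scale <- exp(stats::rnorm(7, 0, config$day_sd))
  noise <- matrix(exp(stats::rnorm(7 * 24, 0, config$noise_sd)), 7, 24)
  raw <- (day_scale %o% shape) * noise * 100
  raw <- raw * (100 / max(raw))
  raw <- pmin(pmax(round(raw), 0), 100)
  weekly_popularity(raw)
}

sample_range <- function(r) {
  if (r[1L] == r[2L]) r[1L] else sample(r[1L]:r[2L], 1L)
}

gen_one_park <- function(park_id, center, config, est_offset) {
  n_areas <- sample_range(config$target_areas_per_park)
  ax <- center[1L] + stats::runif(n_areas, -150, 150)
  ay <- center[2L] + stats::runif(n_areas, -150, 150)
  areas <- target_areas(park_id, sprintf("%s_a%02d", park_id, seq_len(n_areas)),
                        x = ax, y = ay)
  buffer <- build_buffer(areas, config$buffer_radius_m)
  lo <- log(config$establishments_per_park[1L])
  hi <- log(config$establishments_per_park[2L])
  m <- max(1L, round(exp(stats::runif(1, lo, hi))))
  ext <- config$buffer_radius_m + 150
  ex <- center[1L] + stats::runif(m, -ext, ext)
  ey <- center[2L] + stats::runif(m, -ext, ext)
  types <- sample(names(config$type_weights), m, replace = TRUE,
                  prob = config$type_weights)
  syn <- default_raw_synonyms()
  raw <- vapply(types, function(tp) {
    cand <- syn[[tp]]
    if (is.null(cand)) tp else cand[sample.int(length(cand), 1L)]
  }, character(1))
  observed <- stats::runif(m) < config$popularity_coverage
  weekly <- vector("list", m)
  for (k in which(observed)) {
    weekly[[k]] <- gen_popularity(types[[k]], config)
  }
  est <- establishments(sprintf("e%06d", est_offset + seq_len(m)),
                        ex, ey, raw, type = types, weekly = weekly)
  list(areas = areas, buffer = buffer, est = est)
}

#' Generate a complete synthetic study
#'
#' Lays parks out on a well-separated grid with jittered point target areas,
#' scatters typed establishments around each park (a
#' `popularity_coverage` fraction carrying generated weekly popularity),
#' draws CPAT scores, computes each park's true exposure context from the
#' popularity-carrying establishments in its buffer, and draws scan counts
#' from `Poisson(exp(beta . covariates + u_park))` with
#' `u_park ~ N(0, random_intercept_sd^2)`.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes
#'   `target_areas.geojson`, `establishments.json`, `cpat.csv`, `scans.csv`
#'   and `truth.json` there.
#' @return list with `target_areas`, `buffers`, `establishments`, `cpat`,
#'   `scans`, `contexts` (true park-level covariates) and `truth` (all
#'   latent parameters, including the random intercepts and the seed).
#' @export
gen_study <- function(config = sim_config(), dir = NULL) {
  if (!inherits(config, "sim_config")) pa_stop_structural("'config' must be a sim_config")
  set.seed(config$seed)
  n <- config$n_parks
  ncol_grid <- ceiling(sqrt(n))
  spacing <- 4000
  park_ids <- sprintf("park%02d", seq_len(n))
  areas_list <- vector("list", n)
  buffers <- vector("list", n)
  est_list <- vector("list", n)
  offset <- 0L
  for (p in seq_len(n)) {
    center <- c(((p - 1L) %% ncol_grid) * spacing,
                ((p - 1L) %/% ncol_grid) * spacing)
    ok <- FALSE
    for (try in seq_len(config$max_retries)) {
      g <- gen_one_park(park_ids[[p]], center, config, offset)
      in_buf <- select_in_buffer(g$est, g$buffer)
      if (nrow(in_buf) > 0L && any(has_weekly(in_buf))) { ok <- TRUE; break }
    }
    if (!ok) {
      pa_stop_degenerate(sprintf(
        "park '%s': no popularity-carrying establishment in buffer after %d attempts",
        park_ids[[p]], config$max_retries
      ))
    }
    areas_list[[p]] <- g$areas
    buffers[[p]] <- g$buffer
    est_list[[p]] <- g$est
    offset <- offset + nrow(g$est)
  }
  target_areas_df <- do.call(rbind, areas_list)
  est <- do.call(rbind, est_list)
  names(buffers) <- park_ids

  dom <- matrix(pmin(100, pmax(0, stats::rnorm(6L * n, config$cpat_mean,
                                               config$cpat_sd))), n, 6L)
  cpat <- data.frame(park_id = park_ids, dom, stringsAsFactors = FALSE)
  names(cpat) <- c("park_id", paste0("domain", 1:6))
  cpat$overall <- apply(cpat[, paste0("domain", 1:6)], 1L, cpat_overall)

  # true covariates: the popularity-carrying establishments in each buffer
  observed <- est[has_weekly(est), , drop = FALSE]
  contexts <- compute_park_contexts(observed, buffers, cpat)

  beta <- config$true_beta
  u <- stats::rnorm(n, 0, config$random_intercept_sd)
  covmat <- if (config$effect_scale == "standardized") {
    cbind(contexts$n_types_z, contexts$l2_z, contexts$n_establishments_z,
          contexts$cpat_z)
  } else {
    cbind(contexts$n_types, contexts$l2, contexts$n_establishments_z,
          contexts$cpat)
  }
  eta_park <- beta[["intercept"]] +
    drop(covmat %*% beta[c("n_types", "l2", "n_establishments_z", "cpat")]) + u

  scan_rows <- vector("list", n)
  for (p in seq_len(n)) {
    aid <- areas_list[[p]]$area_id
    n_areas <- length(aid)
    nv <- config$visits_per_park
    periods_per <- vapply(seq_len(nv), function(v)
      sample_range(config$periods_per_visit), integer(1))
    P <- sum(periods_per)
    visit_of_period <- rep(seq_len(nv), periods_per)
    index_in_visit <- sequence(periods_per)
    rounds_per <- sample(1:4, P, replace = TRUE, prob = config$rounds_weights)
    # one block of rows per (period, round); each block scans every area once
    period_of_block <- rep(seq_len(P), rounds_per)
    round_of_block <- sequence(rounds_per)
    df <- data.frame(
      park_id = park_ids[[p]],
      area_id = rep(aid, times = length(period_of_block)),
      visit_id = rep(sprintf("%s_v%d", park_ids[[p]],
                             visit_of_period[period_of_block]),
                     each = n_areas),
      period_id = rep(sprintf("%s_v%d_p%d", park_ids[[p]],
                              visit_of_period[period_of_block],
                              index_in_visit[period_of_block]),
                      each = n_areas),
      round_index = rep(round_of_block, each = n_areas),
      stringsAsFactors = FALSE
    )
    df$count <- stats::rpois(nrow(df), exp(eta_park[[p]]))
    scan_rows[[p]] <- df
  }
  scans <- do.call(rbind, scan_rows)
  rownames(scans) <- NULL

  truth <- list(
    seed = config$seed,
    effect_scale = config$effect_scale,
    true_beta = as.list(beta),
    random_intercept_sd = config$random_intercept_sd,
    random_intercepts = stats::setNames(as.list(u), park_ids),
    eta_park = stats::setNames(as.list(eta_park), park_ids)
  )

  out <- list(target_areas = target_areas_df, buffers = buffers,
              establishments = est, cpat = cpat, scans = scans,
              contexts = contexts, truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_target_areas(target_areas_df, file.path(dir, "target_areas.geojson"))
    write_establishments_json(est, file.path(dir, "establishments.json"))
    utils::write.csv(cpat, file.path(dir, "cpat.csv"), row.names = FALSE)
    utils::write.csv(scans, file.path(dir, "scans.csv"), row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
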