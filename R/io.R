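# Tabular and JSON input/output: establishments (with or without weekly
# popularity), flat popularity CSV, SOPARC scans, CPAT scores.

day_names <- c("Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
               "Saturday", "Sunday")

#' Assemble an establishment table
#'
#' @param id identifiers (coerced to character; must be unique).
#' @param x,y projected metric coordinates.
#' @param raw_category raw category strings (the primary category).
#' @param type optional broad types; if missing, map later via
#'   [map_category()].
#' @param weekly optional list of [weekly_popularity()] matrices (or NULL
#'   entries for establishments without observed popularity).
#' @return data frame with list column `weekly`.
#' @export
establishments <- function(id, x, y, raw_category, type = NULL, weekly = NULL) {
  id <- as.character(id)
  n <- length(id)
  if (anyDuplicated(id)) pa_stop_structural("establishment ids must be unique")
  if (!is_finite_num(x) || !is_finite_num(y) ||
      length(x) != n || length(y) != n) {
    pa_stop_structural("establishment coordinates must be finite, one per id")
  }
  df <- data.frame(id = id, x = x, y = y,
                   raw_category = as.character(raw_category),
                   stringsAsFactors = FALSE)
  if (!is.null(type)) df$type <- as.character(type)
  if (is.null(weekly)) weekly <- vector("list", n)
  if (length(weekly) != n) {
    pa_stop_structural("'weekly' must have one entry (possibly NULL) per establishment")
  }
  df$weekly <- lapply(weekly, function(w) {
    if (is.null(w)) NULL else weekly_popularity(w)
  })
  df
}

has_weekly <- function(est) {
  !vapply(est$weekly, is.null, logical(1))
}

#' Read establishments from CSV
#'
#' Columns: `id`, `x`, `y`, `raw_category`. Weekly popularity, if available
#' in the flat CSV dialect, can be attached with [read_popularity_csv()].
#'
#' @param path CSV file.
#' @return an [establishments()] data frame (all `weekly` entries NULL).
#' @export
read_establishments_csv <- function(path) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("establishment file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "raw_category")
  if (!all(need %in% names(df))) {
    pa_stop_structural(sprintf("establishment CSV needs columns: %s",
                               paste(need, collapse = ", ")))
  }
  establishments(df$id, df$x, df$y, df$raw_category)
}

#' Read/attach weekly popularity in the flat CSV dialect
#'
#' Flat dialect: columns `establishment_id`, `day` (0 = Monday ... 6 =
#' Sunday), `hour` (0--23), `popularity` (integer 0--100); one row per cell,
#' 168 rows per establishment.
#'
#' @param path CSV file in the flat dialect.
#' @param est optional [establishments()] table to attach the matrices to
#'   (matched on `id`).
#' @return if `est` is NULL, a named list of [weekly_popularity()] matrices;
#'   otherwise `est` with its `weekly` column filled where ids match.
#' @export
read_popularity_csv <- function(path, est = NULL) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("popularity file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("establishment_id", "day", "hour", "popularity")
  if (!all(need %in% names(df))) {
    pa_stop_structural(sprintf("popularity CSV needs columns: %s",
                               paste(need, collapse = ", ")))
  }
  mats <- lapply(split(df, as.character(df$establishment_id)), function(d) {
    if (nrow(d) != 168L) {
      pa_stop_structural(sprintf(
        "establishment '%s' has %d popularity rows (need 168)",
        d$establishment_id[[1L]], nrow(d)
      ))
    }
    m <- matrix(0L, 7L, 24L)
    m[cbind(d$day + 1L, d$hour + 1L)] <- d$popularity
    weekly_popularity(m)
  })
  if (is.null(est)) return(mats)
  idx <- match(est$id, names(mats))
  est$weekly <- lapply(seq_along(idx), function(k) {
    if (is.na(idx[k])) est$weekly[[k]] else mats[[idx[k]]]
  })
  est
}

#' Write weekly popularity in the flat CSV dialect
#'
#' @param est an [establishments()] table; rows without popularity are
#'   skipped.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_popularity_csv <- function(est, path) {
  keep <- which(has_weekly(est))
  rows <- lapply(keep, function(k) {
    m <- unclass(est$weekly[[k]])
    data.frame(
      establishment_id = est$id[[k]],
      day = rep(0:6, times = 24L),
      hour = rep(0:23, each = 7L),
      popularity = as.integer(m),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows) %||%
    data.frame(establishment_id = character(), day = integer(),
               hour = integer(), popularity = integer())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read establishments from the popularity JSON dialect
#'
#' One JSON array of establishment records mirroring a Popular Times
#' payload: fields `id`, `x`, `y`, `raw_category` (or a `categories` array,
#' first entry primary), and optionally `populartimes`: an array of seven
#' `{"name": "Monday", "data": [24 ints]}` objects.
#'
#' @param path JSON file.
#' @return an [establishments()] data frame.
#' @export
read_establishments_json <- function(path) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("establishment file not found: %s", path))
  }
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(recs) == 0L) pa_stop_structural("establishment JSON is empty")
  id <- vapply(recs, function(r) as.character(r$id %||% NA_character_), character(1))
  x <- vapply(recs, function(r) as.numeric(r$x %||% NA_real_), numeric(1))
  y <- vapply(recs, function(r) as.numeric(r$y %||% NA_real_), numeric(1))
  raw <- vapply(recs, function(r) {
    if (!is.null(r$categories)) {
      primary_category(unlist(r$categories, use.names = FALSE))
    } else {
      as.character(r$raw_category %||% NA_character_)
    }
  }, character(1))
  weekly <- lapply(recs, function(r) {
    pt <- r$populartimes
    if (is.null(pt)) return(NULL)
    m <- matrix(0L, 7L, 24L)
    for (d in pt) {
      row <- match(d$name, day_names)
      if (is.na(row)) pa_stop_structural(sprintf("unknown day name '%s'", d$name))
      vals <- as.integer(unlist(d$data, use.names = FALSE))
      if (length(vals) != 24L) {
        pa_stop_structural(sprintf("day '%s' does not carry 24 hourly values", d$name))
      }
      m[row, ] <- vals
    }
    m
  })
  establishments(id, x, y, raw, weekly = weekly)
}

#' Write establishments in the popularity JSON dialect
#'
#' @param est an [establishments()] table.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_establishments_json <- function(est, path) {
  recs <- lapply(seq_len(nrow(est)), function(k) {
    r <- list(id = est$id[[k]], x = est$x[[k]], y = est$y[[k]],
              raw_category = est$raw_category[[k]])
    w <- est$weekly[[k]]
    if (!is.null(w)) {
      m <- unclass(w)
      r$populartimes <- lapply(1:7, function(d) {
        list(name = day_names[[d]], data = as.integer(m[d, ]))
      })
    }
    r
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write establishments coordinates/categories as CSV
#'
#' @param est an [establishments()] table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_establishments_csv <- function(est, path) {
  utils::write.csv(est[, c("id", "x", "y", "raw_category")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read SOPARC-style scan records
#'
#' Columns: `park_id`, `area_id`, `visit_id`, `period_id`, `round_index`
#' (positive integer), `count` (non-negative integer persons per scan).
#'
#' @param path CSV file.
#' @return validated scan data frame.
#' @export
read_scans <- function(path) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("scan file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_scans(df)
}

validate_scans <- function(df) {
  need <- c("park_id", "area_id", "visit_id", "period_id", "round_index",
            "count")
  if (!is.data.frame(df) || !all(need %in% names(df))) {
    pa_stop_structural(sprintf("scan table needs columns: %s",
                               paste(need, collapse = ", ")))
  }
  if (nrow(df) > 0L) {
    if (!is.numeric(df$count) || any(!is.finite(df$count)) ||
        any(df$count < 0) || any(df$count != round(df$count))) {
      pa_stop_structural("scan counts must be non-negative integers")
    }
    if (!is.numeric(df$round_index) || any(df$round_index < 1) ||
        any(df$round_index != round(df$round_index))) {
      pa_stop_structural("round_index must be a positive integer")
    }
  }
  df$park_id <- as.character(df$park_id)
  df$area_id <- as.character(df$area_id)
  df
}

#' Read CPAT park-quality scores
#'
#' Expects `park_id` plus six already-standardized (0--100) domain columns;
#' the overall score is their mean.
#'
#' @param path CSV file.
#' @return data frame with `park_id`, the six domain columns and `overall`.
#' @export
read_cpat <- function(path) {
  if (!file.exists(path)) {
    pa_stop_structural(sprintf("CPAT file not found: %s", path))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"park_id" %in% names(df)) pa_stop_structural("CPAT CSV needs a park_id column")
  dom <- setdiff(names(df), c("park_id", "overall"))
  if (length(dom) != 6L) {
    pa_stop_structural(sprintf(
      "CPAT CSV must carry exactly six domain columns (found %d)", length(dom)
    ))
  }
  df$park_id <- as.character(df$park_id)
  df$overall <- apply(df[, dom], 1L, cpat_overall)
  df
}
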