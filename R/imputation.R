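#' Nearest same-type popularity imputation
#'
#' Assigns to each establishment lacking an observed weekly popularity
#' matrix a copy of the matrix of the nearest (planar Euclidean distance,
#' projected meters) establishment of the same broad type that has one.
#' Establishments already carrying popularity pass through unchanged. Ties
#' in distance are broken deterministically by the lexicographically
#' smallest reference id.
#'
#' @param est an [establishments()] table with a `type` column; rows whose
#'   `weekly` entry is NULL are imputation targets.
#' @param references optional separate reference table (with `type` and
#'   non-NULL `weekly`); by default the rows of `est` that carry popularity.
#' @param policy what to do for a target whose type has no reference
#'   anywhere: `"strict"` errors; `"lenient"` falls back to the nearest
#'   reference of any type and flags the row in the provenance record.
#' @return a list with `establishments` (all rows now carrying `weekly`) and
#'   `provenance`: a data frame `target_id`, `source_id`, `distance_m`,
#'   `fallback` (one row per imputed establishment).
#' @export
impute_popularity <- function(est, references = NULL,
                              policy = c("strict", "lenient")) {
  policy <- match.arg(policy)
  if (!is.data.frame(est) || is.null(est$weekly)) {
    pa_stop_structural("'est' must be an establishments table with a weekly column")
  }
  if (is.null(est$type)) {
    pa_stop_structural("establishments must carry a broad 'type' before imputation")
  }
  if (is.null(references)) {
    references <- est[has_weekly(est), , drop = FALSE]
  }
  if (!is.data.frame(references) || nrow(references) == 0L ||
      !all(has_weekly(references))) {
    pa_stop_structural("'references' must be non-empty and all carry weekly popularity")
  }
  if (is.null(references$type)) {
    pa_stop_structural("references must carry a broad 'type'")
  }
  targets <- which(!has_weekly(est))
  prov <- data.frame(target_id = character(0), source_id = character(0),
                     distance_m = numeric(0), fallback = logical(0),
                     stringsAsFactors = FALSE)
  if (length(targets) == 0L) {
    return(list(establishments = est, provenance = prov))
  }
  t_type <- est$type[targets]
  pick <- integer(length(targets))
  fallback <- logical(length(targets))
  for (tp in unique(t_type)) {
    ti <- which(t_type == tp)
    ri <- which(references$type == tp)
    fb <- FALSE
    if (length(ri) == 0L) {
      if (policy == "strict") {
        pa_stop_structural(sprintf(
          "no reference establishment of type '%s' available for imputation", tp
        ))
      }
      ri <- seq_len(nrow(references))
      fb <- TRUE
    }
    d <- cross_dist(est$x[targets[ti]], est$y[targets[ti]],
                    references$x[ri], references$y[ri])
    # nearest with lexicographic id tie-break: order candidate refs by id so
    # which.min keeps the smallest id among exactly-equal distances
    ord <- order(as.character(references$id[ri]))
    d <- d[, ord, drop = FALSE]
    ri <- ri[ord]
    j <- apply(d, 1L, which.min)
    pick[ti] <- ri[j]
    fallback[ti] <- fb
  }
  dist_m <- sqrt((est$x[targets] - references$x[pick])^2 +
                 (est$y[targets] - references$y[pick])^2)
  est$weekly[targets] <- references$weekly[pick]
  prov <- data.frame(
    target_id = est$id[targets],
    source_id = as.character(references$id[pick]),
    distance_m = dist_m,
    fallback = fallback,
    stringsAsFactors = FALSE
  )
  list(establishments = est, provenance = prov)
}

#' Write an imputation provenance record
#'
#' @param provenance the `provenance` element of [impute_popularity()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  utils::write.csv(provenance, path, row.names = FALSE)
  invisible(path)
}
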