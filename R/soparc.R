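#' Overall CPAT park-quality score
#'
#' The Community Park Audit Tool summarizes park quality in six domain
#' scores, each already standardized to a 0--100 scale; the overall park
#' score is their arithmetic mean.
#'
#' @param domain_scores numeric vector of exactly six values in `[0, 100]`.
#' @return the mean of the six domains.
#' @export
cpat_overall <- function(domain_scores) {
  domain_scores <- as.numeric(domain_scores)
  if (length(domain_scores) != 6L || !all(is.finite(domain_scores))) {
    pa_stop_structural("CPAT requires exactly six finite domain scores")
  }
  if (any(domain_scores < 0 | domain_scores > 100)) {
    pa_stop_structural("CPAT domain scores must lie in [0, 100]")
  }
  mean(domain_scores)
}

#' Z-score standardization across parks
#'
#' Centers and scales to sample standard deviation 1 (divisor `n - 1`).
#' Used to put the establishment-count covariate on a comparable effect
#' scale across analyses.
#'
#' @param values numeric vector, one value per park, length >= 2.
#' @return standardized vector (mean 0, sample SD 1).
#' @export
standardize <- function(values) {
  if (!is_finite_num(values) || length(values) < 2L) {
    pa_stop_structural("standardization needs >= 2 finite values")
  }
  s <- stats::sd(values)
  if (s == 0) pa_stop_degenerate("cannot standardize a constant vector")
  (values - mean(values)) / s
}

#' Per-park exposure contexts
#'
#' Computes the park-level exposure measures from establishments and
#' buffers: land-use density (`n_establishments`), commercial activity
#' diversity (`n_types`), and the L2 norm of the buffer's daily activation
#' distribution (plus its windowed sensitivity variant), joined to CPAT
#' quality. `n_establishments` is additionally Z-standardized across parks;
#' per-SD versions of the other exposures (`n_types_z`, `l2_z`, `cpat_z`)
#' are provided for simulation work.
#'
#' @param est an [establishments()] table with `type`; the L2 measures use
#'   the subset of rows carrying weekly popularity.
#' @param buffers named list of [build_buffer()] objects (names or
#'   `park_id`s identify parks).
#' @param cpat data frame with `park_id` and `overall` (see [read_cpat()]),
#'   or NULL to skip the quality covariate.
#' @param window integer pair for the windowed L2 (default `c(9, 19)`).
#' @return data frame, one row per park.
#' @export
compute_park_contexts <- function(est, buffers, cpat = NULL,
                                  window = c(9, 19)) {
  if (length(buffers) == 0L) pa_stop_structural("no buffers supplied")
  rows <- lapply(buffers, function(b) {
    sel <- select_in_buffer(est, b)
    obs <- sel[has_weekly(sel), , drop = FALSE]
    if (nrow(obs) == 0L) {
      pa_stop_degenerate(sprintf(
        "park '%s': no establishment in the buffer carries popularity", b$park_id
      ))
    }
    dailies <- lapply(obs$weekly, mean_daily)
    data.frame(
      park_id = b$park_id,
      n_establishments = nrow(sel),
      n_types = count_types(sel),
      l2 = park_l2(dailies),
      l2_windowed = l2_norm_windowed(dailies, window[[1L]], window[[2L]]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(cpat)) {
    idx <- match(out$park_id, cpat$park_id)
    if (anyNA(idx)) {
      pa_stop_structural(sprintf(
        "no CPAT score for park '%s'", out$park_id[which(is.na(idx))[1L]]
      ))
    }
    out$cpat <- cpat$overall[idx]
  }
  out$n_establishments_z <- standardize(out$n_establishments)
  # auxiliary per-SD columns for simulation work; a measure that happens to
  # be constant across parks gives NA here rather than an error
  safe_z <- function(x) if (stats::sd(x) == 0) rep(NA_real_, length(x)) else
    standardize(x)
  out$n_types_z <- safe_z(out$n_types)
  out$l2_z <- safe_z(out$l2)
  if (!is.null(out$cpat)) out$cpat_z <- safe_z(out$cpat)
  validate_park_contexts(out)
  out
}

validate_park_contexts <- function(ctx) {
  if (!is.data.frame(ctx) || !all(c("park_id", "n_establishments", "n_types",
                                    "l2") %in% names(ctx))) {
    pa_stop_structural("park contexts need park_id, n_establishments, n_types, l2")
  }
  bad <- ctx$n_establishments > 0 & ctx$n_types > ctx$n_establishments
  if (any(bad)) {
    pa_stop_structural(sprintf(
      "park '%s': more types than establishments", ctx$park_id[bad][1L]
    ))
  }
  lo <- 1 / sqrt(24) - 1e-9
  if (any(ctx$l2 < lo | ctx$l2 > 1 + 1e-9)) {
    pa_stop_structural("park L2 norm outside [1/sqrt(24), 1]")
  }
  invisible(ctx)
}

#' Build the scan-level analysis table
#'
#' Joins every scan's person count to its park's exposure context; one row
#' per scan, clustered by park. The join never alters counts.
#'
#' @param scans scan records (see [read_scans()]).
#' @param contexts per-park contexts (see [compute_park_contexts()]); must
#'   cover every park appearing in `scans`.
#' @return data frame with one row per scan: scan identifiers, `count`, the
#'   park exposures, and a `cluster` factor (the park).
#' @export
build_analysis_table <- function(scans, contexts) {
  scans <- validate_scans(scans)
  if (nrow(scans) == 0L) {
    out <- cbind(scans, contexts[0, setdiff(names(contexts), "park_id"),
                                 drop = FALSE])
    out$cluster <- factor(character(0))
    return(out)
  }
  idx <- match(scans$park_id, contexts$park_id)
  if (anyNA(idx)) {
    pa_stop_structural(sprintf(
      "scan references park '%s' with no context",
      scans$park_id[which(is.na(idx))[1L]]
    ))
  }
  out <- cbind(scans,
               contexts[idx, setdiff(names(contexts), "park_id"),
                        drop = FALSE])
  rownames(out) <- NULL
  out$cluster <- factor(out$park_id)
  out
}
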