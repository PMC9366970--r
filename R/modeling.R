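# Poisson generalized estimating equations with parks as clusters.
#
# Fisher scoring on the GEE estimating function with an exchangeable (or
# independence) working correlation. For a cluster with mean mu and
# A = diag(mu), the Poisson variance function gives A^(1/2) = diag(sqrt(mu))
# and, writing s = sqrt(mu), the working-inverse algebra collapses to
#   D'V^-1 D  =  c1 [ X' A X - c2 (X's)(X's)' ]
#   D'V^-1 e  =  c1 X' [ e - c2 s sum(e/s) ]
# with c1 = 1/(1-alpha), c2 = alpha / (1 + (n_i - 1) alpha); the scale
# parameter cancels from both the update and the sandwich. Cluster-robust
# variance is the usual B^-1 M B^-1 with M the outer-product meat.

gee_poisson <- function(y, X, cluster, corstr = c("exchangeable", "independence"),
                        correction = c("mancl-derouen", "none"),
                        maxit = 100L, tol = 1e-10) {
  corstr <- match.arg(corstr)
  correction <- match.arg(correction)
  if (!is.numeric(y) || any(!is.finite(y)) || any(y < 0)) {
    pa_stop_structural("outcome must be non-negative and finite")
  }
  X <- as.matrix(X)
  if (!all(is.finite(X))) pa_stop_structural("model matrix contains non-finite values")
  if (nrow(X) != length(y)) pa_stop_structural("outcome and model matrix sizes differ")
  cluster <- factor(cluster)
  n_clusters <- nlevels(cluster)
  if (n_clusters < 2L) {
    pa_stop_structural("GEE requires at least two clusters")
  }
  p <- ncol(X)
  N <- length(y)
  idx <- split(seq_len(N), cluster)

  fit0 <- suppressWarnings(stats::glm.fit(X, y, family = stats::poisson()))
  beta <- fit0$coefficients
  if (anyNA(beta)) pa_stop_structural("model matrix is rank deficient")

  alpha <- 0
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    res <- (y - mu) / sqrt(mu) # Pearson
    phi <- sum(res^2) / (N - p)
    if (corstr == "exchangeable") {
      num <- 0; den <- 0
      for (ix in idx) {
        ri <- res[ix]; ni <- length(ri)
        if (ni > 1L) {
          num <- num + (sum(ri)^2 - sum(ri * ri)) / 2
          den <- den + ni * (ni - 1L) / 2
        }
      }
      if (den <= p) pa_stop_structural("too few within-cluster pairs to estimate alpha")
      alpha <- num / phi / (den - p)
      # keep the working correlation positive definite
      nmax <- max(lengths(idx))
      alpha <- max(min(alpha, 0.999), -0.999 / (nmax - 1))
    }
    B <- matrix(0, p, p)
    u <- numeric(p)
    for (ix in idx) {
      Xi <- X[ix, , drop = FALSE]
      mui <- mu[ix]; si <- sqrt(mui); ei <- y[ix] - mui
      ni <- length(ix)
      c1 <- 1 / (1 - alpha)
      c2 <- alpha / (1 + (ni - 1) * alpha)
      Xs <- crossprod(Xi, si)               # X' s
      B <- B + c1 * (crossprod(Xi, Xi * mui) - c2 * tcrossprod(Xs))
      u <- u + c1 * crossprod(Xi, ei - c2 * si * sum(ei / si))
    }
    step <- solve(B, u)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol * (1 + max(abs(beta)))) {
      converged <- TRUE
      break
    }
  }

  # sandwich at the final beta/alpha; with the Mancl-DeRouen bias
  # correction each cluster score is premultiplied by (I - B_i B^-1)^-1
  # (the Woodbury form of (I - H_ii)^-1 applied inside D' V^-1), which
  # counteracts the downward bias of the plain sandwich when the number of
  # clusters is modest
  eta <- drop(X %*% beta); mu <- exp(eta)
  B <- matrix(0, p, p)
  Bi_list <- vector("list", length(idx))
  ui_list <- vector("list", length(idx))
  k <- 0L
  for (ix in idx) {
    k <- k + 1L
    Xi <- X[ix, , drop = FALSE]
    mui <- mu[ix]; si <- sqrt(mui); ei <- y[ix] - mui
    ni <- length(ix)
    c1 <- 1 / (1 - alpha)
    c2 <- alpha / (1 + (ni - 1) * alpha)
    Xs <- crossprod(Xi, si)
    Bi <- c1 * (crossprod(Xi, Xi * mui) - c2 * tcrossprod(Xs))
    B <- B + Bi
    Bi_list[[k]] <- Bi
    ui_list[[k]] <- c1 * crossprod(Xi, ei - c2 * si * sum(ei / si))
  }
  Binv <- solve(B)
  M <- matrix(0, p, p)
  Ip <- diag(p)
  for (k in seq_along(ui_list)) {
    ui <- ui_list[[k]]
    if (correction == "mancl-derouen") {
      # (I - H_ii) is singular when a cluster has leverage one (possible
      # when the cluster count barely exceeds the parameter count); fall
      # back to the Moore-Penrose inverse there
      A <- Ip - Bi_list[[k]] %*% Binv
      ui <- tryCatch(solve(A, ui), error = function(e) {
        sv <- svd(A)
        pos <- sv$d > max(sv$d) * 1e-10
        sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], ui)) / sv$d[pos])
      })
    }
    M <- M + tcrossprod(ui)
  }
  vcov <- Binv %*% M %*% Binv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  list(beta = beta, vcov = vcov, alpha = if (corstr == "exchangeable") alpha else NA_real_,
       corstr = corstr, correction = correction, converged = converged,
       iterations = it, n_obs = N, n_clusters = n_clusters)
}

#' Model specification for the battery
#'
#' The three model configurations: `types_only` (diversity), `l2_only`
#' (activation evenness), and `types_plus_l2` (both, for the
#' mediation-attenuation comparison). Every specification controls for the
#' Z-standardized establishment count and the CPAT quality score.
#'
#' @param name one of `"types_only"`, `"l2_only"`, `"types_plus_l2"`.
#' @return a `model_spec` list with elements `name` and `covariates`.
#' @export
model_spec <- function(name = c("types_only", "l2_only", "types_plus_l2")) {
  name <- match.arg(name)
  covariates <- switch(name,
    types_only = c("n_types", "n_establishments_z", "cpat"),
    l2_only = c("l2", "n_establishments_z", "cpat"),
    types_plus_l2 = c("n_types", "l2", "n_establishments_z", "cpat")
  )
  structure(list(name = name, covariates = covariates), class = "model_spec")
}

#' Fit a Poisson GEE for scan counts clustered by park
#'
#' Fits a log-linear Poisson marginal model for scan-level person counts
#' with a working correlation over scans within the same park and
#' cluster-robust (sandwich) standard errors. 95% confidence intervals are
#' `estimate +/- 1.96 * robust SE` on the log scale. Because designs of
#' this kind have a modest number of clusters (parks), the robust variance
#' uses the Mancl-DeRouen bias-corrected sandwich by default; set
#' `correction = "none"` for the classical (uncorrected) sandwich.
#'
#' @param table analysis table from [build_analysis_table()] (needs `count`,
#'   `cluster`, and the covariate columns).
#' @param spec a [model_spec()] or its name; ignored if `covariates` given.
#' @param covariates optional explicit character vector of covariate column
#'   names (overrides `spec`).
#' @param corstr working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param correction small-sample correction of the robust covariance:
#'   `"mancl-derouen"` (default) or `"none"`.
#' @return a `gee_fit` object: `coefficients` data frame (term, estimate,
#'   se, ci_low, ci_high, z, p, significant), `vcov`, `alpha`, `n_obs`,
#'   `n_clusters`, `converged`.
#' @export
fit_gee <- function(table, spec = "types_only", covariates = NULL,
                    corstr = c("exchangeable", "independence"),
                    correction = c("mancl-derouen", "none")) {
  corstr <- match.arg(corstr)
  correction <- match.arg(correction)
  if (!is.data.frame(table) || nrow(table) == 0L) {
    pa_stop_structural("analysis table is empty")
  }
  if (is.character(spec)) spec <- model_spec(spec)
  covs <- covariates %||% spec$covariates
  miss <- setdiff(c("count", "cluster", covs), names(table))
  if (length(miss) > 0L) {
    pa_stop_structural(sprintf("analysis table lacks columns: %s",
                               paste(miss, collapse = ", ")))
  }
  X <- cbind("(Intercept)" = 1, as.matrix(table[, covs, drop = FALSE]))
  res <- gee_poisson(table$count, X, table$cluster, corstr = corstr,
                     correction = correction)
  if (!res$converged) {
    warning("GEE did not converge within the iteration limit", call. = FALSE)
  }
  se <- sqrt(diag(res$vcov))
  est <- res$beta
  z <- est / se
  pval <- 2 * stats::pnorm(-abs(z))
  coefs <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - 1.96 * se),
    ci_high = unname(est + 1.96 * se),
    z = unname(z),
    p = unname(pval),
    significant = unname(pval < 0.05),
    stringsAsFactors = FALSE
  )
  structure(
    list(spec = if (is.null(covariates)) spec else
           list(name = "custom", covariates = covs),
         coefficients = coefs, vcov = res$vcov, alpha = res$alpha,
         corstr = res$corstr, correction = res$correction, n_obs = res$n_obs,
         n_clusters = res$n_clusters, converged = res$converged,
         iterations = res$iterations),
    class = "gee_fit"
  )
}

#' @export
print.gee_fit <- function(x, ...) {
  cat(sprintf("Poisson GEE (%s working correlation), %d scans in %d parks%s\n",
              x$corstr, x$n_obs, x$n_clusters,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (!is.na(x$alpha)) cat(sprintf("estimated alpha: %.4f\n", x$alpha))
  df <- x$coefficients
  df$estimate <- sprintf("%.3f", df$estimate)
  df$ci <- sprintf("(%.3f, %.3f)%s", x$coefficients$ci_low,
                   x$coefficients$ci_high,
                   ifelse(x$coefficients$significant, "*", ""))
  print(df[, c("term", "estimate", "ci")], row.names = FALSE)
  invisible(x)
}

#' Run the three-model battery with attenuation report
#'
#' Fits `types_only`, `l2_only` and `types_plus_l2` in that fixed order and
#' reports how the diversity (`n_types`) coefficient changes when the
#' hypothesized mediator (the L2 norm) enters the model: under mediation the
#' joint-model diversity effect should be attenuated toward zero.
#'
#' @inheritParams fit_gee
#' @return a `gee_battery`: list with `fits` (named list of three
#'   [fit_gee()] results) and `attenuation` (one-row data frame with the
#'   diversity coefficient alone and jointly, their difference, and the L2
#'   coefficients).
#' @export
run_model_battery <- function(table, corstr = c("exchangeable", "independence"),
                              correction = c("mancl-derouen", "none")) {
  corstr <- match.arg(corstr)
  correction <- match.arg(correction)
  specs <- c("types_only", "l2_only", "types_plus_l2")
  fits <- lapply(specs, function(s)
    fit_gee(table, spec = s, corstr = corstr, correction = correction))
  names(fits) <- specs
  coef_of <- function(fit, term) {
    fit$coefficients$estimate[fit$coefficients$term == term]
  }
  b_alone <- coef_of(fits$types_only, "n_types")
  b_joint <- coef_of(fits$types_plus_l2, "n_types")
  attenuation <- data.frame(
    b_types_alone = b_alone,
    b_types_joint = b_joint,
    attenuation = abs(b_alone) - abs(b_joint),
    b_l2_alone = coef_of(fits$l2_only, "l2"),
    b_l2_joint = coef_of(fits$types_plus_l2, "l2"),
    stringsAsFactors = FALSE
  )
  structure(list(fits = fits, attenuation = attenuation),
            class = "gee_battery")
}

#' @export
print.gee_battery <- function(x, ...) {
  for (nm in names(x$fits)) {
    cat("==", nm, "==\n")
    print(x$fits[[nm]])
    cat("\n")
  }
  cat(sprintf(
    "diversity coefficient: %.4f alone, %.4f with L2 (attenuation %.4f)\n",
    x$attenuation$b_types_alone, x$attenuation$b_types_joint,
    x$attenuation$attenuation))
  invisible(x)
}

#' Tidy battery results in a results-table layout
#'
#' @param battery a [run_model_battery()] result.
#' @return data frame with columns model, term, b, ci_low, ci_high,
#'   significant.
#' @export
battery_results <- function(battery) {
  rows <- lapply(names(battery$fits), function(nm) {
    cf <- battery$fits[[nm]]$coefficients
    data.frame(model = nm, term = cf$term, b = cf$estimate,
               ci_low = cf$ci_low, ci_high = cf$ci_high,
               significant = cf$significant, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlation between two per-park measure sets
#'
#' Pearson correlation with the two-sided p-value from the t distribution
#' on `n - 2` degrees of freedom; used to compare the observed-data and
#' imputed-data versions of each park-level measure.
#'
#' @param x,y numeric vectors of equal length >= 3 (one value per park).
#' @return list with `r`, `p`, and `n`.
#' @export
compare_measures <- function(x, y) {
  if (!is_finite_num(x) || !is_finite_num(y) || length(x) != length(y) ||
      length(x) < 3L) {
    pa_stop_structural("measure comparison needs two equal-length numeric vectors, n >= 3")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    pa_stop_degenerate("cannot correlate a constant measure")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
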