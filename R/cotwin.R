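#' Within-twin-pair association estimate
#'
#' The conditional (fixed-pair) estimator for a linear outcome, computed
#' by within-pair mean-centering of outcome, exposure, and covariates:
#' algebraically identical to OLS on twin differences, and to the
#' conditional estimating-equation point estimate for linear models.
#' Covariates that are constant within every pair (e.g. age, sex of
#' same-sex pairs) drop out of the centered design and are removed
#' automatically.
#'
#' @param pairs data frame with columns \code{pair_id}, \code{zygosity},
#'   an exposure column, an outcome column and optional covariates (e.g. a
#'   [simulate_twin_cohort()] table).
#' @param zygosity \code{"MZ"}, \code{"DZ"}, or \code{NULL} for all pairs.
#' @param exposure,outcome column names (defaults \code{"biomarker"},
#'   \code{"fi"}).
#' @param covariates character vector of covariate column names.
#' @return one-row data frame: beta, se, n_pairs, n_dropped, zygosity.
#' @export
within_pair_estimate <- function(pairs, zygosity = NULL,
                                 exposure = "biomarker", outcome = "fi",
                                 covariates = character()) {
  d <- as.data.frame(pairs)
  if (!is.null(zygosity)) d <- d[d$zygosity == zygosity, , drop = FALSE]
  vars <- c(exposure, outcome, covariates)
  cc <- stats::complete.cases(d[vars])
  d <- d[cc, , drop = FALSE]
  tab <- table(d$pair_id)
  complete_pairs <- names(tab)[tab == 2L]
  n_dropped <- length(tab) - length(complete_pairs)
  d <- d[d$pair_id %in% complete_pairs, , drop = FALSE]
  if (length(complete_pairs) < 2L)
    stopf("fewer than 2 complete %s pairs", zygosity %||% "twin")
  center <- function(v) v - stats::ave(v, d$pair_id)
  yc <- center(d[[outcome]])
  xc <- center(d[[exposure]])
  if (stats::var(xc) == 0)
    stopf("no within-pair exposure variance; estimate undefined")
  X <- xc
  for (cv in covariates) {
    cvc <- center(as.numeric(d[[cv]]))
    if (stats::var(cvc) > 0) X <- cbind(X, cvc)
  }
  X <- as.matrix(X)
  fit <- stats::lm.fit(X, yc)
  # centered data have one redundant row per pair: df = n_pairs - k
  n_pairs <- length(complete_pairs)
  res <- fit$residuals
  sigma2 <- sum(res^2) / (n_pairs - ncol(X))
  XtXinv <- chol2inv(chol(crossprod(X)))
  data.frame(beta = unname(fit$coefficients[1L]),
             se = sqrt(sigma2 * XtXinv[1L, 1L]),
             n_pairs = n_pairs, n_dropped = n_dropped,
             zygosity = zygosity %||% "all", stringsAsFactors = FALSE)
}

#' Co-twin control comparison of population and within-pair estimates
#'
#' Applies the co-twin interpretation logic: if both within-pair
#' confidence intervals cover the population point estimate the pattern is
#' consistent with causality; if the magnitudes order population > DZ > MZ
#' with the MZ interval covering zero, the pattern suggests genetic
#' confounding (MZ twins share all segregating genes, DZ about half); if
#' DZ and MZ attenuate similarly while both differ from the population
#' estimate, shared environment; anything else is inconclusive.
#'
#' @param population one-row data frame with \code{beta} and \code{se}
#'   (e.g. from [fit_linear_assoc()] with cluster-robust SEs).
#' @param dz,mz one-row data frames from [within_pair_estimate()].
#' @param similar_tol relative tolerance for "similar attenuation" of DZ
#'   and MZ (default 0.25 of the population estimate's magnitude).
#' @return object of class \code{cotwin_fit}: estimates, attenuation
#'   ratios and interpretation label (one of causal-consistent,
#'   genetic-confounding-pattern, shared-environment-pattern,
#'   inconclusive).
#' @export
cotwin_compare <- function(population, dz, mz, similar_tol = 0.25) {
  ci <- function(e) c(e$beta - 1.96 * e$se, e$beta + 1.96 * e$se)
  covers <- function(e, value) {
    lim <- ci(e); value >= lim[1L] && value <= lim[2L]
  }
  pop_b <- population$beta
  # within-pair intervals covering both zero and the population estimate
  # carry no information either way
  uninformative <- covers(dz, 0) && covers(dz, pop_b) &&
    covers(mz, 0) && covers(mz, pop_b)
  label <-
    if (uninformative) {
      "inconclusive"
    } else if (covers(dz, pop_b) && covers(mz, pop_b) &&
        !(covers(mz, 0) && abs(mz$beta) < 0.5 * abs(pop_b))) {
      "causal-consistent"
    } else if (abs(pop_b) > abs(dz$beta) && abs(dz$beta) > abs(mz$beta) &&
               covers(mz, 0)) {
      "genetic-confounding-pattern"
    } else if (abs(dz$beta - mz$beta) <= similar_tol * abs(pop_b) &&
               abs(mz$beta) < abs(pop_b) && abs(dz$beta) < abs(pop_b)) {
      "shared-environment-pattern"
    } else {
      "inconclusive"
    }
  structure(list(
    population = population, dz = dz, mz = mz,
    attenuation = c(dz_vs_pop = dz$beta / pop_b, mz_vs_pop = mz$beta / pop_b),
    label = label
  ), class = "cotwin_fit")
}

#' @export
print.cotwin_fit <- function(x, ...) {
  cat("Co-twin control comparison\n")
  cat(sprintf("  population: %.4f (SE %.4f)\n", x$population$beta, x$population$se))
  cat(sprintf("  within DZ : %.4f (SE %.4f)\n", x$dz$beta, x$dz$se))
  cat(sprintf("  within MZ : %.4f (SE %.4f)\n", x$mz$beta, x$mz$se))
  cat(sprintf("  attenuation DZ/pop = %.2f, MZ/pop = %.2f\n",
              x$attenuation[1L], x$attenuation[2L]))
  cat("  interpretation:", x$label, "\n")
  invisible(x)
}
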