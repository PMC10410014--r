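#' Standardize biomarker values within a sample
#'
#' Centers to mean 0 and scales to sample SD 1 (denominator n-1), the
#' convention that puts association estimates on the "per SD increase in
#' biomarker" scale and makes effect sizes comparable across biomarkers
#' with different units.
#'
#' @param x numeric vector or matrix (columns standardized independently).
#' @return z-scores with the same shape as \code{x}.
#' @export
standardize <- function(x) {
  if (is.matrix(x) || is.data.frame(x)) {
    x <- as.matrix(x)
    return(apply(x, 2L, standardize))
  }
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 2L)
    stopf("cannot standardize a constant biomarker%s",
          if (!is.null(names(x))) paste0(" '", names(x)[1L], "'") else "")
  (x - mean(x[ok])) / stats::sd(x[ok])
}

#' Flag biomarker values far from the median
#'
#' Keeps a value iff it lies within \code{k} interquartile ranges of the
#' median (default 5), the rule used for outlier sensitivity reruns.  A
#' zero IQR keeps everything with a warning.
#'
#' @param x numeric vector.
#' @param k IQR multiplier, default 5.
#' @return logical keep mask (missing values are kept as \code{NA}-safe
#'   \code{TRUE} so complete-case handling decides their fate downstream).
#' @export
filter_outliers <- function(x, k = 5) {
  med <- stats::median(x, na.rm = TRUE)
  iqr <- stats::IQR(x, na.rm = TRUE)
  if (iqr == 0) {
    warning("IQR is zero; no values filtered")
    return(rep(TRUE, length(x)))
  }
  keep <- abs(x - med) <= k * iqr
  keep[is.na(keep)] <- TRUE
  keep
}

#' Bonferroni per-test significance threshold
#'
#' @param m number of tests in the family (e.g. 200 biomarkers).
#' @param alpha family-wise error rate, default 0.05.
#' @return alpha / m (0.05/200 = 0.00025 for the canonical 200-biomarker
#'   family).
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stopf("family size must be at least 1")
  alpha / m
}

#' Linear biomarker-frailty association with optional cluster-robust SEs
#'
#' Ordinary least squares of the frailty outcome (FI \% or FP score) on a
#' standardized biomarker plus covariates, on complete cases.  With
#' \code{cluster_ids} (e.g. twin-pair ids) standard errors use the CR1
#' cluster-robust sandwich; with clusters of size one this reduces to the
#' HC1 heteroskedasticity-robust estimator.
#'
#' @param outcome numeric outcome vector.
#' @param biomarker numeric vector of biomarker z-scores.
#' @param covariates optional data frame of covariates (factors are
#'   reference-coded with their first level as reference).
#' @param cluster_ids optional vector of cluster labels.
#' @param id label stored in the result.
#' @param model tag stored in the result (e.g. "base", "fully_adjusted").
#' @return one-row data frame of class \code{assoc_result}: id, beta, se,
#'   ci_low, ci_high, p, n, model, cluster_robust, n_dropped.
#' @export
fit_linear_assoc <- function(outcome, biomarker, covariates = NULL,
                             cluster_ids = NULL, id = "biomarker",
                             model = "base") {
  df <- data.frame(.y = outcome, .z = biomarker)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  cc <- stats::complete.cases(df)
  n_dropped <- sum(!cc)
  df <- df[cc, , drop = FALSE]
  if (!is.null(cluster_ids)) cluster_ids <- cluster_ids[cc]
  X <- stats::model.matrix(~ ., data = df[, -1L, drop = FALSE])
  if (nrow(X) <= ncol(X) + 1L)
    stopf("too few complete cases (%d) for %d parameters", nrow(X), ncol(X))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stopf("rank-deficient design; collinear columns: %s",
          paste(drop_cols, collapse = ", "))
  }
  fit <- stats::lm.fit(X, df$.y)
  coefs <- fit$coefficients
  res <- fit$residuals
  n <- nrow(X); k <- ncol(X)
  XtXinv <- chol2inv(chol(crossprod(X)))
  if (is.null(cluster_ids)) {
    sigma2 <- sum(res^2) / (n - k)
    V <- sigma2 * XtXinv
    robust <- FALSE
  } else {
    V <- cr1_vcov(X, res, cluster_ids, XtXinv)
    robust <- TRUE
  }
  j <- match(".z", colnames(X))
  beta <- unname(coefs[j]); se <- sqrt(V[j, j])
  out <- data.frame(id = id, beta = beta, se = se,
                    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                    p = 2 * stats::pnorm(-abs(beta / se)),
                    n = n, model = model, cluster_robust = robust,
                    n_dropped = n_dropped, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

# CR1 cluster-robust sandwich: c * (X'X)^-1 [sum_g (X_g'e_g)(X_g'e_g)'] (X'X)^-1
# with c = G/(G-1) * (n-1)/(n-k)
cr1_vcov <- function(X, res, cluster_ids, XtXinv) {
  n <- nrow(X); k <- ncol(X)
  Xe <- X * res
  S <- rowsum(Xe, group = as.character(cluster_ids))
  G <- nrow(S)
  meat <- crossprod(S)
  corr <- G / (G - 1) * (n - 1) / (n - k)
  corr * XtXinv %*% meat %*% XtXinv
}

#' Run the discovery association screen
#'
#' Fits one covariate-adjusted linear model per biomarker (optionally per
#' stratum) and flags results against the Bonferroni threshold for the
#' family size actually tested.
#'
#' @param data data frame holding outcome, biomarkers and covariates.
#' @param outcome name of the outcome column (FI or FP).
#' @param biomarkers character vector of biomarker column names (assumed
#'   already standardized; standardize with [standardize()] first).
#' @param covariates character vector of covariate column names.
#' @param strata optional named list of logical row masks; the screen is
#'   rerun inside each stratum (family threshold unchanged per stratum).
#' @param cluster_col optional name of a cluster-id column for
#'   cluster-robust SEs.
#' @param alpha family-wise error rate for the Bonferroni flag.
#' @param family_size size of the testing family; defaults to the number
#'   of biomarkers screened.
#' @param model tag recorded on every result.
#' @return data frame of class \code{screen_result}: one row per biomarker
#'   (x stratum) with a \code{flag} column; attributes \code{threshold}
#'   and \code{family_size}.
#' @export
run_screen <- function(data, outcome, biomarkers, covariates = character(),
                       strata = NULL, cluster_col = NULL,
                       alpha = 0.05, family_size = length(biomarkers),
                       model = "base") {
  stopifnot(outcome %in% names(data), all(biomarkers %in% names(data)),
            all(covariates %in% names(data)))
  thr <- bonferroni_threshold(family_size, alpha)
  run_one <- function(rows, stratum_label) {
    d <- data[rows, , drop = FALSE]
    res <- lapply(biomarkers, function(b) {
      fit_linear_assoc(
        outcome = d[[outcome]], biomarker = d[[b]],
        covariates = if (length(covariates)) d[covariates] else NULL,
        cluster_ids = if (!is.null(cluster_col)) d[[cluster_col]] else NULL,
        id = b,
        model = if (is.na(stratum_label)) model
                else paste0(model, ":", stratum_label))
    })
    do.call(rbind, res)
  }
  if (is.null(strata)) {
    out <- run_one(rep(TRUE, nrow(data)), NA_character_)
  } else {
    parts <- list()
    for (nm in names(strata)) {
      rows <- strata[[nm]]
      if (!any(rows, na.rm = TRUE)) {
        warning("stratum '", nm, "' is empty; skipped")
        next
      }
      parts[[nm]] <- run_one(rows & !is.na(rows), nm)
    }
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
  }
  out$flag <- out$p < thr
  attr(out, "threshold") <- thr
  attr(out, "family_size") <- family_size
  class(out) <- c("screen_result", "data.frame")
  out
}
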