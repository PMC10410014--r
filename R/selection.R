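#' LASSO selection of independently associated biomarkers
#'
#' Fits the penalized regression
#' (1/2n)||y - X b - C g||^2 + lambda ||b||_1 with mandatory covariates C
#' (age, sex, ...) left unpenalized, chooses lambda by seeded 10-fold
#' cross-validation with the one-standard-error rule (the largest lambda
#' whose CV mean squared error is within one SE of the minimum), and
#' returns the biomarkers with nonzero coefficients at that lambda.
#' Fitting and cross-validation are delegated to \pkg{glmnet}.
#'
#' @param X numeric matrix of standardized biomarkers (n x p, named
#'   columns).  Non-standardized input triggers a warning and internal
#'   standardization.
#' @param y numeric outcome (FI \%, unstandardized).
#' @param mandatory optional numeric matrix of unpenalized covariates.
#' @param n_folds number of CV folds, default 10.
#' @param seed integer seed controlling the fold assignment; mandatory.
#' @return object of class \code{lasso_result}: list with
#'   \code{lambda_path}, \code{cv_mse}, \code{cv_se}, \code{lambda_min},
#'   \code{lambda_1se}, \code{coefficients} (at lambda_1se, penalized and
#'   mandatory terms), \code{selected} (biomarker ids with nonzero
#'   coefficient), and \code{foldid}.
#' @export
lasso_select <- function(X, y, mandatory = NULL, n_folds = 10L, seed) {
  if (missing(seed)) stopf("seed is mandatory (controls CV fold assignment)")
  if (n_folds < 2L) stopf("n_folds must be at least 2")
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (nrow(X) <= n_folds) stopf("need more observations than folds")
  mu <- colMeans(X); sdx <- apply(X, 2L, stats::sd)
  if (max(abs(mu)) > 1e-6 || max(abs(sdx - 1)) > 1e-6) {
    warning("X does not look standardized; standardizing internally")
    X <- standardize(X)
  }
  p <- ncol(X)
  if (!is.null(mandatory)) {
    mandatory <- as.matrix(mandatory)
    if (is.null(colnames(mandatory)))
      colnames(mandatory) <- paste0("c", seq_len(ncol(mandatory)))
    Xall <- cbind(X, mandatory)
    pf <- c(rep(1, p), rep(0, ncol(mandatory)))
  } else {
    Xall <- X
    pf <- rep(1, p)
  }
  foldid <- withr::with_seed(seed,
    sample(rep_len(seq_len(n_folds), nrow(Xall))))
  cv <- glmnet::cv.glmnet(Xall, y, family = "gaussian",
                          penalty.factor = pf, foldid = foldid,
                          standardize = FALSE, type.measure = "mse")
  co <- stats::coef(cv, s = "lambda.1se")
  co <- stats::setNames(as.numeric(co), rownames(co))
  selected <- names(co)[co != 0]
  selected <- setdiff(intersect(selected, colnames(X)), "(Intercept)")
  structure(list(
    lambda_path = cv$lambda,
    cv_mse = cv$cvm,
    cv_se = cv$cvsd,
    lambda_min = cv$lambda.min,
    lambda_1se = cv$lambda.1se,
    coefficients = co,
    selected = selected,
    foldid = foldid,
    fit = cv$glmnet.fit
  ), class = "lasso_result")
}

#' @export
print.lasso_result <- function(x, ...) {
  cat("LASSO selection (1-SE rule)\n")
  cat(sprintf("  lambda_min = %.5g, lambda_1se = %.5g\n",
              x$lambda_min, x$lambda_1se))
  cat(sprintf("  %d biomarker(s) selected: %s\n", length(x$selected),
              paste(utils::head(x$selected, 10L), collapse = ", ")))
  invisible(x)
}
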