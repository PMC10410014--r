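# Two-sample MR estimators.  All take a harmonized_instruments set and
# return an mr_estimate (list): method, beta, se, ci_low, ci_high, p,
# n_snp, plus method-specific diagnostics.

new_mr_estimate <- function(method, beta, se, n_snp, ...) {
  structure(c(list(method = method, beta = beta, se = se,
                   ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                   p = 2 * stats::pnorm(-abs(beta / se)), n_snp = n_snp),
              list(...)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4f (SE %.4f, 95%% CI %.4f to %.4f), p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$p, x$n_snp))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  intercept = %.4f (p = %.3g)\n",
                x$egger_intercept, x$intercept_p))
  if (!is.null(x$Q))
    cat(sprintf("  Q = %.3f (df %d, p = %.3g)\n", x$Q, x$n_snp - 1L, x$Q_p))
  if (!is.null(x$outlier_ids) && length(x$outlier_ids))
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Inverse-variance-weighted MR (multiplicative random effects)
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights se_Y^-2: theta = sum(bX bY w) / sum(bX^2 w), fixed
#' SE = (sum bX^2 w)^-1/2, inflated by max(1, sqrt(Q/(J-1))) under the
#' multiplicative random-effects model.
#'
#' @param set a [harmonize()]d instrument set with at least 2 SNPs.
#' @return an \code{mr_estimate} with Cochran's Q attached.
#' @export
mr_ivw <- function(set) {
  J <- nrow(set)
  if (J < 2L) stopf("IVW requires at least 2 SNPs (use mr_wald_ratio for 1)")
  w <- 1 / set$se_outcome^2
  bx <- set$beta_exposure; by <- set$beta_outcome
  theta <- sum(bx * by * w) / sum(bx^2 * w)
  se_fixed <- 1 / sqrt(sum(bx^2 * w))
  Q <- sum(w * (by - theta * bx)^2)
  se <- se_fixed * max(1, sqrt(Q / (J - 1)))
  new_mr_estimate("IVW", theta, se, J, Q = Q,
                  Q_p = stats::pchisq(Q, J - 1L, lower.tail = FALSE))
}

#' Single-SNP Wald ratio
#'
#' Fallback estimator when instrument pruning leaves one SNP: the ratio
#' beta_Y / beta_X with first-order delta-method SE se_Y / |beta_X|.
#'
#' @param set a harmonized set with exactly 1 SNP.
#' @return an \code{mr_estimate} labeled \code{"Wald_ratio"}.
#' @export
mr_wald_ratio <- function(set) {
  if (nrow(set) != 1L) stopf("Wald ratio is defined for a single SNP")
  new_mr_estimate("Wald_ratio", set$ratio, set$ratio_se, 1L)
}

#' MR-Egger regression
#'
#' Weighted regression beta_Y = alpha + theta beta_X with weights se_Y^-2
#' after orienting every SNP so beta_X >= 0 (Egger is not orientation
#' invariant).  The intercept alpha estimates the average directional
#' pleiotropic effect under the InSIDE assumption; SEs are inflated by
#' max(1, sqrt(Q_egger/(J-2))).
#'
#' @param set a harmonized set with at least 3 SNPs.
#' @return an \code{mr_estimate} with \code{egger_intercept},
#'   \code{intercept_se}, \code{intercept_p} and the Egger Q.
#' @export
mr_egger <- function(set) {
  J <- nrow(set)
  if (J < 3L) stopf("MR-Egger requires at least 3 SNPs")
  flip <- set$beta_exposure < 0
  bx <- abs(set$beta_exposure)
  by <- ifelse(flip, -set$beta_outcome, set$beta_outcome)
  w <- 1 / set$se_outcome^2
  X <- cbind(1, bx)
  fit <- stats::lm.wfit(X, by, w)
  coefs <- fit$coefficients
  rss_w <- sum(w * fit$residuals^2)
  XtWXinv <- chol2inv(chol(crossprod(X * sqrt(w))))
  scale <- max(1, sqrt(rss_w / (J - 2)))
  ses <- sqrt(diag(XtWXinv)) * scale
  est <- new_mr_estimate("Egger", unname(coefs[2L]), ses[2L], J,
                         Q = rss_w,
                         Q_p = stats::pchisq(rss_w, J - 2L, lower.tail = FALSE),
                         egger_intercept = unname(coefs[1L]),
                         intercept_se = ses[1L],
                         intercept_p = 2 * stats::pnorm(-abs(coefs[1L] / ses[1L])))
  est
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]; w <- weights[ord] / sum(weights)
  p <- cumsum(w) - w / 2
  if (0.5 <= p[1L]) return(b[1L])
  if (0.5 >= p[length(p)]) return(b[length(b)])
  stats::approx(p, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimator
#'
#' The weighted median of the per-SNP Wald ratios (inverse-variance
#' weights, percentile interpolation), consistent when instruments
#' carrying over 50\% of the weight are valid.  The SE comes from a seeded
#' parametric bootstrap resampling both betas from their sampling
#' distributions.
#'
#' @param set a harmonized set with at least 3 SNPs.
#' @param n_boot bootstrap repetitions, default 1000.
#' @param seed integer seed for the bootstrap; mandatory.
#' @return an \code{mr_estimate}.
#' @export
mr_weighted_median <- function(set, n_boot = 1000L, seed) {
  if (missing(seed)) stopf("seed is mandatory for the bootstrap SE")
  J <- nrow(set)
  if (J < 3L) stopf("weighted median requires at least 3 SNPs")
  est <- weighted_median_point(set$ratio, 1 / set$ratio_se^2)
  se <- boot_ratio_se(set, n_boot, seed, weighted_median_point)
  new_mr_estimate("weighted_median", est, se, J)
}

boot_ratio_se <- function(set, n_boot, seed, point_fun, ...) {
  J <- nrow(set)
  withr::with_seed(seed, {
    bx <- matrix(stats::rnorm(J * n_boot, set$beta_exposure, set$se_exposure), J)
    by <- matrix(stats::rnorm(J * n_boot, set$beta_outcome, set$se_outcome), J)
    ests <- vapply(seq_len(n_boot), function(s) {
      r <- by[, s] / bx[, s]
      rs <- set$se_outcome / abs(bx[, s])
      point_fun(r, 1 / rs^2, ...)
    }, 0)
    stats::sd(ests)
  })
}

weighted_mode_point <- function(ratios, weights, phi = 1) {
  w <- weights / sum(weights)
  J <- length(ratios)
  s <- weighted_sd(ratios, w)
  iqr <- diff(weighted_quantile(ratios, w, c(0.25, 0.75)))
  h <- phi * 0.9 * min(s, iqr / 1.34) * J^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(ratios[which.max(w)])
  grid <- seq(min(ratios), max(ratios), length.out = 512L)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - ratios) / h)) / h, 0)
  grid[which.max(dens)]
}

#' Weighted-mode MR estimator
#'
#' The mode of the inverse-variance-weighted normal-kernel density of the
#' per-SNP Wald ratios (bandwidth h = phi * 0.9 * min(weighted SD,
#' weighted IQR/1.34) * J^(-1/5), argmax on a 512-point grid), consistent
#' when a plurality of instruments is valid.  SE by seeded parametric
#' bootstrap.
#'
#' @param set a harmonized set with at least 3 SNPs.
#' @param phi bandwidth multiplier, default 1.
#' @param n_boot bootstrap repetitions, default 1000.
#' @param seed integer seed; mandatory.
#' @return an \code{mr_estimate}.
#' @export
mr_weighted_mode <- function(set, phi = 1, n_boot = 1000L, seed) {
  if (missing(seed)) stopf("seed is mandatory for the bootstrap SE")
  J <- nrow(set)
  if (J < 3L) stopf("weighted mode requires at least 3 SNPs")
  est <- weighted_mode_point(set$ratio, 1 / set$ratio_se^2, phi)
  se <- boot_ratio_se(set, n_boot, seed, weighted_mode_point, phi)
  new_mr_estimate("weighted_mode", est, se, J)
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' For each SNP the residual against the leave-one-out IVW fit is
#' compared with its distribution under no pleiotropy, simulated from the
#' per-SNP sampling distributions.  The observed global weighted RSS gives
#' a global pleiotropy p-value; per-SNP simulation p-values are
#' Bonferroni-corrected and SNPs below \code{outlier_alpha} are flagged.
#' The corrected estimate is IVW on the remaining SNPs.
#'
#' @param set a harmonized set with at least 4 SNPs.
#' @param n_sim number of simulated datasets, default 1000.
#' @param outlier_alpha flagging threshold on the Bonferroni-corrected
#'   per-SNP p, default 0.05.
#' @param seed integer seed; mandatory.
#' @return list of class \code{mr_presso}: \code{raw} and
#'   \code{corrected} \code{mr_estimate}s, \code{global_p},
#'   \code{outlier_ids}, per-SNP \code{outlier_p}.
#' @export
mr_presso <- function(set, n_sim = 1000L, outlier_alpha = 0.05, seed) {
  if (missing(seed)) stopf("seed is mandatory for the simulation")
  J <- nrow(set)
  if (J < 4L) stopf("MR-PRESSO requires at least 4 SNPs")
  w <- 1 / set$se_outcome^2
  bx <- set$beta_exposure; by <- set$beta_outcome

  loo_theta <- function(bx, by, w) {
    sxy <- sum(bx * by * w); sxx <- sum(bx^2 * w)
    (sxy - bx * by * w) / (sxx - bx^2 * w)
  }
  th_loo <- loo_theta(bx, by, w)
  res_obs <- w * (by - th_loo * bx)^2
  rss_obs <- sum(res_obs)

  withr::with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(J * n_sim, bx, set$se_exposure), J)
    by_sim <- matrix(stats::rnorm(J * n_sim, th_loo * bx, set$se_outcome), J)
    res_sim <- matrix(0, J, n_sim)
    for (s in seq_len(n_sim)) {
      th_s <- loo_theta(bx_sim[, s], by_sim[, s], w)
      res_sim[, s] <- w * (by_sim[, s] - th_s * bx_sim[, s])^2
    }
  })
  rss_sim <- colSums(res_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + rowSums(res_sim >= res_obs)) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * J)
  flagged <- outlier_p < outlier_alpha
  raw <- mr_ivw(set)
  raw$method <- "PRESSO_raw"
  if (any(flagged) && sum(!flagged) >= 2L) {
    corrected <- mr_ivw(set[!flagged, , drop = FALSE])
    corrected$method <- "PRESSO_corrected"
  } else {
    corrected <- raw
    corrected$method <- "PRESSO_corrected"
  }
  structure(list(raw = raw, corrected = corrected, global_p = global_p,
                 outlier_ids = set$variant_id[flagged],
                 outlier_p = stats::setNames(outlier_p, set$variant_id)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: global p = %.3g, %d outlier(s)\n",
              x$global_p, length(x$outlier_ids)))
  print(x$raw); print(x$corrected)
  invisible(x)
}

#' Cochran's Q heterogeneity test across instruments
#'
#' Q = sum w_j (ratio_j - theta)^2 with w_j = ratio_se_j^-2, referred to a
#' chi-square distribution on J-1 degrees of freedom.
#'
#' @param set a harmonized set with at least 2 SNPs.
#' @param theta causal estimate to test against (e.g. the IVW estimate).
#' @return list with Q, df, p.
#' @export
cochran_q <- function(set, theta) {
  J <- nrow(set)
  if (J < 2L) stopf("Cochran's Q requires at least 2 SNPs")
  w <- 1 / set$ratio_se^2
  Q <- sum(w * (set$ratio - theta)^2)
  list(Q = Q, df = J - 1L,
       p = stats::pchisq(Q, J - 1L, lower.tail = FALSE))
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure at level \code{q}; also reports the largest rejected
#' raw p-value, the data-dependent significance threshold that studies
#' quote (e.g. "p < 0.011 at 5\% FDR").
#'
#' @param pvals numeric p-values in \[0,1\].
#' @param q FDR level, default 0.05.
#' @return list with \code{adjusted} (BH-adjusted p-values),
#'   \code{reject} (logical), \code{threshold} (largest rejected raw p, or
#'   \code{NA} when nothing is rejected).
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stopf("p-values must lie in [0,1]")
  adjusted <- stats::p.adjust(pvals, method = "BH")
  reject <- !is.na(adjusted) & adjusted <= q
  threshold <- if (any(reject)) max(pvals[reject]) else NA_real_
  list(adjusted = adjusted, reject = reject, threshold = threshold)
}
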