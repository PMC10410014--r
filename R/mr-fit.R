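#' Fit the two-sample MR estimator suite to one instrument set
#'
#' The central model-fitting entry point: runs the requested estimators
#' (multiplicative random-effects IVW as the primary method, MR-Egger,
#' weighted median, weighted mode, MR-PRESSO) on a harmonized instrument
#' set and collects them in one object.  With a single instrument the fit
#' falls back to the Wald ratio, labeled distinctly.
#'
#' @param set a [harmonize()]d instrument set.
#' @param methods subset of \code{c("ivw", "egger", "weighted_median",
#'   "weighted_mode", "presso")}.
#' @param n_boot bootstrap repetitions for median/mode SEs.
#' @param n_sim MR-PRESSO simulation count.
#' @param seed integer seed for the stochastic methods; mandatory when any
#'   of them is requested.
#' @param phi weighted-mode bandwidth multiplier.
#' @return object of class \code{mr_fit}: list of \code{mr_estimate}s plus
#'   the instrument set and heterogeneity diagnostics.  Methods whose
#'   minimum SNP count is not met are skipped with a note.
#' @seealso [coef.mr_fit()], [confint.mr_fit()], [plot.mr_fit()]
#' @export
mr_fit <- function(set,
                   methods = c("ivw", "egger", "weighted_median",
                               "weighted_mode", "presso"),
                   n_boot = 1000L, n_sim = 1000L, seed = NULL, phi = 1) {
  methods <- match.arg(methods, several.ok = TRUE)
  J <- nrow(set)
  if (J == 0L) stopf("empty instrument set")
  needs_seed <- any(methods %in% c("weighted_median", "weighted_mode", "presso")) && J >= 3L
  if (needs_seed && is.null(seed))
    stopf("seed is mandatory for bootstrap/simulation-based methods")
  estimates <- list()
  skipped <- character(0)
  if (J == 1L) {
    estimates$wald_ratio <- mr_wald_ratio(set)
    skipped <- setdiff(methods, character(0))
  } else {
    for (m in methods) {
      min_j <- c(ivw = 2L, egger = 3L, weighted_median = 3L,
                 weighted_mode = 3L, presso = 4L)[[m]]
      if (J < min_j) { skipped <- c(skipped, m); next }
      estimates[[m]] <- switch(m,
        ivw = mr_ivw(set),
        egger = mr_egger(set),
        weighted_median = mr_weighted_median(set, n_boot, seed = seed),
        weighted_mode = mr_weighted_mode(set, phi, n_boot, seed = seed),
        presso = mr_presso(set, n_sim, seed = seed))
    }
  }
  het <- if (J >= 2L && !is.null(estimates$ivw))
    cochran_q(set, estimates$ivw$beta) else NULL
  structure(list(estimates = estimates, set = set, heterogeneity = het,
                 skipped = skipped, n_snp = J,
                 f_statistics = f_statistic(set)),
            class = "mr_fit")
}

as_estimate_rows <- function(fit) {
  rows <- list()
  for (est in fit$estimates) {
    if (inherits(est, "mr_presso")) {
      for (e in list(est$raw, est$corrected))
        rows[[length(rows) + 1L]] <- data.frame(
          method = e$method, beta = e$beta, se = e$se,
          ci_low = e$ci_low, ci_high = e$ci_high, p = e$p, n_snp = e$n_snp,
          Q = e$Q %||% NA_real_, Q_p = e$Q_p %||% NA_real_,
          egger_intercept = NA_real_, intercept_p = NA_real_,
          global_p = est$global_p,
          outlier_ids = paste(est$outlier_ids, collapse = ";"),
          stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        method = est$method, beta = est$beta, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, p = est$p,
        n_snp = est$n_snp,
        Q = est$Q %||% NA_real_, Q_p = est$Q_p %||% NA_real_,
        egger_intercept = est$egger_intercept %||% NA_real_,
        intercept_p = est$intercept_p %||% NA_real_,
        global_p = NA_real_, outlier_ids = "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR fit on %d instrument(s) (min F = %.1f)\n",
              x$n_snp, x$f_statistics$min_f))
  for (est in x$estimates) print(est)
  if (!is.null(x$heterogeneity))
    cat(sprintf("Cochran's Q = %.3f (df %d, p = %.3g)\n",
                x$heterogeneity$Q, x$heterogeneity$df, x$heterogeneity$p))
  if (length(x$skipped))
    cat("skipped (too few SNPs):", paste(x$skipped, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  out <- as_estimate_rows(object)
  attr(out, "f_statistics") <- object$f_statistics
  class(out) <- c("summary.mr_fit", "data.frame")
  out
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn mr_fit named vector of causal-effect point estimates.
#' @param object,... method arguments.
#' @export
coef.mr_fit <- function(object, ...) {
  rows <- as_estimate_rows(object)
  stats::setNames(rows$beta, rows$method)
}

#' @describeIn mr_fit per-method normal-approximation confidence intervals.
#' @param parm ignored.
#' @param level confidence level.
#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  rows <- as_estimate_rows(object)
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(rows$beta - z * rows$se, rows$beta + z * rows$se)
  dimnames(out) <- list(rows$method,
                        sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                                   1 - (1 - level) / 2)))
  out
}

#' @describeIn mr_fit scatter of SNP-outcome against SNP-exposure effects
#'   with the fitted slopes.
#' @param x an \code{mr_fit}.
#' @export
plot.mr_fit <- function(x, ...) {
  set <- x$set
  flip <- set$beta_exposure < 0
  bx <- abs(set$beta_exposure)
  by <- ifelse(flip, -set$beta_outcome, set$beta_outcome)
  graphics::plot(bx, by, pch = 19, col = "grey30",
                 xlab = "SNP effect on exposure (per SD)",
                 ylab = "SNP effect on outcome",
                 main = "Two-sample MR", ...)
  graphics::segments(bx, by - 1.96 * set$se_outcome,
                     bx, by + 1.96 * set$se_outcome, col = "grey70")
  cols <- c(IVW = "firebrick", Egger = "steelblue",
            weighted_median = "darkgreen", weighted_mode = "orange")
  for (est in x$estimates) {
    if (inherits(est, "mr_presso")) next
    cl <- cols[est$method]
    if (is.na(cl)) next
    if (est$method == "Egger")
      graphics::abline(a = est$egger_intercept, b = est$beta, col = cl, lwd = 2)
    else
      graphics::abline(a = 0, b = est$beta, col = cl, lwd = 2)
  }
  graphics::legend("topleft", legend = names(cols), col = cols, lwd = 2,
                   bty = "n", cex = 0.8)
  invisible(x)
}

#' Run the MR estimator battery over exposures and frailty outcomes
#'
#' For every exposure x outcome pair: select instruments at the
#' significance threshold, clump, harmonize, and fit the requested
#' estimators.  Benjamini-Hochberg FDR control is applied across the
#' primary IVW family (exposures x the primary outcomes, by default FI and
#' FP); the stripped-FI outcomes are sensitivity reruns outside the FDR
#' family.  Per-pair failures are logged and the battery continues.
#'
#' @param exposures named list of exposure summary-statistics data frames,
#'   or of lists with elements \code{summary_stats} and optional \code{ld}.
#' @param outcomes named list of outcome summary-statistics data frames
#'   (e.g. \code{FI}, \code{FP}, and 11 stripped-FI outcomes).
#' @param primary_outcomes outcome names making up the FDR family
#'   (default intersection of \code{c("FI","FP")} with the outcome names).
#' @param methods estimators to run, as in [mr_fit()].
#' @param p_threshold,r2_threshold,window_kb,palindromic_maf instrument
#'   selection and harmonization thresholds (defaults 5e-8, 0.001,
#'   10000 kb, 0.42).
#' @param fdr_q FDR level, default 0.05.
#' @param n_boot,n_sim bootstrap / simulation sizes.
#' @param seed integer seed; mandatory when stochastic methods are run.
#' @return data frame of class \code{mr_battery}: one row per exposure x
#'   outcome x method with estimate fields, \code{fdr_q} adjusted p-values
#'   on the primary IVW rows, and attributes \code{fdr_family_size},
#'   \code{fdr_threshold}, \code{log}, \code{fits}.
#' @export
run_mr_battery <- function(exposures, outcomes,
                           primary_outcomes = intersect(c("FI", "FP"),
                                                        names(outcomes)),
                           methods = c("ivw", "egger", "weighted_median",
                                       "weighted_mode", "presso"),
                           p_threshold = 5e-8, r2_threshold = 0.001,
                           window_kb = 10000, palindromic_maf = 0.42,
                           fdr_q = 0.05, n_boot = 1000L, n_sim = 1000L,
                           seed = NULL) {
  stopifnot(length(names(exposures)) == length(exposures),
            length(names(outcomes)) == length(outcomes))
  rows <- list(); fits <- list(); log <- character(0)
  for (ex_nm in names(exposures)) {
    ex <- exposures[[ex_nm]]
    ld <- NULL
    if (!is.data.frame(ex)) { ld <- ex$ld; ex <- ex$summary_stats }
    iv <- tryCatch(
      select_instruments(ex, p_threshold, ld, r2_threshold, window_kb),
      warning = function(w) { character(0) })
    if (length(iv) == 0L) {
      log <- c(log, sprintf("%s: no instruments at p < %g", ex_nm, p_threshold))
      next
    }
    for (out_nm in names(outcomes)) {
      res <- tryCatch({
        set <- harmonize(ex, outcomes[[out_nm]], iv, palindromic_maf)
        fit <- mr_fit(set, methods, n_boot, n_sim, seed = seed)
        fits[[paste(ex_nm, out_nm, sep = "|")]] <- fit
        cbind(data.frame(exposure = ex_nm, outcome = out_nm,
                         stringsAsFactors = FALSE),
              as_estimate_rows(fit))
      }, error = function(e) {
        log <<- c(log, sprintf("%s x %s failed: %s", ex_nm, out_nm,
                               conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr_q <- NA_real_
  primary <- out$method == "IVW" & out$outcome %in% primary_outcomes
  fdr_threshold <- NA_real_
  if (any(primary)) {
    fdr <- bh_fdr(out$p[primary], fdr_q)
    out$fdr_q[primary] <- fdr$adjusted
    fdr_threshold <- fdr$threshold
  }
  family_size <- sum(primary)
  log <- c(log, sprintf("FDR family size: %d (%d exposure(s) x %d primary outcome(s))",
                        family_size, length(unique(out$exposure[primary])),
                        length(primary_outcomes)))
  attr(out, "fdr_family_size") <- family_size
  attr(out, "fdr_threshold") <- fdr_threshold
  attr(out, "log") <- log
  attr(out, "fits") <- fits
  class(out) <- c("mr_battery", "data.frame")
  out
}
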