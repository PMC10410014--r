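#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-study estimates with the moment-based DerSimonian-Laird
#' between-study variance: fixed-effect weights w_i = se_i^-2, heterogeneity
#' Q = sum w_i (b_i - b_FE)^2, tau^2 = max(0, (Q - (k-1)) /
#' (sum w - sum w^2 / sum w)), random-effects weights 1/(se_i^2 + tau^2).
#' The two-sided p-value uses the normal approximation.  When Q <= k-1 the
#' estimator reduces exactly to fixed-effect inverse-variance pooling.
#'
#' @param betas per-study estimates.
#' @param ses per-study standard errors (all > 0).
#' @param alpha significance level for the replication flag (default 0.05,
#'   strict inequality p < alpha).
#' @return object of class \code{dl_meta}: list with beta, se, ci_low,
#'   ci_high, p, tau2, Q, df, k, replicated.
#' @export
dl_meta <- function(betas, ses, alpha = 0.05) {
  k <- length(betas)
  if (k == 0L) stopf("at least one study is required")
  if (length(ses) != k) stopf("betas and ses must have equal length")
  if (any(ses <= 0)) stopf("all standard errors must be positive")
  w <- 1 / ses^2
  beta_fe <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - beta_fe)^2)
  tau2 <- if (k > 1L) max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  wstar <- 1 / (ses^2 + tau2)
  beta <- sum(wstar * betas) / sum(wstar)
  se <- 1 / sqrt(sum(wstar))
  p <- 2 * stats::pnorm(-abs(beta / se))
  structure(list(beta = beta, se = se,
                 ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
                 p = p, tau2 = tau2, Q = Q, df = k - 1L, k = k,
                 replicated = p < alpha), class = "dl_meta")
}

#' @export
print.dl_meta <- function(x, ...) {
  cat(sprintf(
    "DerSimonian-Laird meta-analysis (k = %d)\n  pooled beta = %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n  p = %.3g, tau^2 = %.4g, Q = %.3f (df %d)\n  %s\n",
    x$k, x$beta, x$se, x$ci_low, x$ci_high, x$p, x$tau2, x$Q, x$df,
    if (x$replicated) "replicated (p < 0.05)" else "not replicated"))
  invisible(x)
}

#' Replication decision for a meta-analyzed association
#'
#' An association counts as replicated when the pooled p-value is strictly
#' below \code{alpha}.  Optionally a direction-consistency requirement
#' against the discovery estimate can be switched on (off by default: the
#' stated criterion is the p-value alone).
#'
#' @param meta a [dl_meta()] result.
#' @param discovery_beta optional discovery-stage estimate.
#' @param require_direction if TRUE additionally require sign agreement
#'   with \code{discovery_beta}.
#' @param alpha significance level (default 0.05).
#' @return logical flag.
#' @export
replication_flag <- function(meta, discovery_beta = NULL,
                             require_direction = FALSE, alpha = 0.05) {
  stopifnot(inherits(meta, "dl_meta"))
  ok <- meta$p < alpha
  if (require_direction && !is.null(discovery_beta))
    ok <- ok && sign(meta$beta) == sign(discovery_beta)
  ok
}
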