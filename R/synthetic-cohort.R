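#' Configuration for a synthetic frailty cohort
#'
#' Describes a cohort of the kind used in biomarker-frailty studies: a
#' panel of block-correlated, within-sample standardized biomarkers; a
#' binary deficit matrix (default 49 items in 11 labeled categories) whose
#' item probabilities follow a logistic function of a single latent frailty
#' liability; and the five frailty-phenotype criteria driven by the same
#' liability.  Biomarker effects are specified on the scale reported in
#' practice: FI percentage points per SD of biomarker, and the generator is
#' calibrated (by quadrature on the liability distribution) so the
#' population regression slope of FI on a biomarker equals its configured
#' effect.
#'
#' @param n_individuals number of individuals.
#' @param n_biomarkers size of the biomarker panel.
#' @param biomarker_blocks list of \code{c(size, rho)} pairs giving
#'   correlated blocks (within-block correlation \code{rho} in \[0,1));
#'   remaining biomarkers are independent.
#' @param true_effects numeric vector (recycled/padded to
#'   \code{n_biomarkers}) of biomarker effects on the FI, in FI \% per SD.
#' @param covariate_effects named numeric vector of covariate effects on
#'   the FI (\% per SD of the covariate); recognised names: \code{age},
#'   \code{sex}, \code{bmi}.
#' @param n_deficit_items number of deficit items (default 49).
#' @param category_map character vector of category labels, one per item;
#'   default assigns 11 categories including an 8-item
#'   \code{"cardiometabolic"} block.
#' @param age_mean_sd length-2 numeric, mean and SD of age in years
#'   (default 56.77 and 8.03).
#' @param fi_target length-2 numeric, target FI mean and SD in percent
#'   (default 12.29 and 7.41); the item intercepts and liability scale are
#'   calibrated against these.
#' @param fp_target_mean target mean frailty-phenotype score (default 0.56).
#' @param seed integer seed; mandatory, never defaulted.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_individuals,
                          n_biomarkers,
                          biomarker_blocks = list(),
                          true_effects = numeric(n_biomarkers),
                          covariate_effects = c(age = 2.0, sex = 0.4),
                          n_deficit_items = 49L,
                          category_map = NULL,
                          age_mean_sd = c(56.77, 8.03),
                          fi_target = c(12.29, 7.41),
                          fp_target_mean = 0.56,
                          seed) {
  if (missing(seed)) stopf("seed is mandatory for synthetic data")
  if (n_individuals < 1L || n_biomarkers < 1L)
    stopf("configuration error: non-positive dimensions")
  for (b in biomarker_blocks) {
    if (length(b) != 2L || b[2L] < 0 || b[2L] >= 1)
      stopf("configuration error: block correlations must lie in [0,1)")
  }
  if (is.null(category_map)) category_map <- default_category_map(n_deficit_items)
  if (length(category_map) != n_deficit_items)
    stopf("category_map must have one label per deficit item")
  if (n_deficit_items < length(unique(category_map)))
    stopf("configuration error: fewer items than categories")
  true_effects <- rep_len(as.numeric(true_effects), n_biomarkers)
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_biomarkers = as.integer(n_biomarkers),
    biomarker_blocks = biomarker_blocks,
    true_effects = true_effects,
    covariate_effects = covariate_effects,
    n_deficit_items = as.integer(n_deficit_items),
    category_map = category_map,
    age_mean_sd = age_mean_sd,
    fi_target = fi_target,
    fp_target_mean = fp_target_mean,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# 11 deficit categories; cardiometabolic holds 8 items as in the 49-item
# index (41 items remain when it is stripped).
default_category_map <- function(n_items) {
  cats <- c("cardiometabolic", "respiratory", "musculoskeletal", "sensory",
            "gastrointestinal", "genitourinary", "neurological", "cancer",
            "immunological", "mental", "functional")
  if (n_items < length(cats)) stopf("need at least 11 items for 11 categories")
  sizes <- rep(floor((n_items - 8L) / 10L), 10L)
  sizes[seq_len((n_items - 8L) %% 10L)] <- sizes[seq_len((n_items - 8L) %% 10L)] + 1L
  rep(cats, times = c(8L, sizes))
}

# Item intercepts: prevalences log-spaced for right skew, shifted so the
# quadrature expectation of the FI matches the target mean at liability
# spread tau.
calibrate_items <- function(n_items, fi_mean_target, tau, rule = gh_rule()) {
  p0 <- exp(seq(log(0.01), log(0.45), length.out = n_items))
  alpha <- stats::qlogis(p0)
  f <- function(delta) {
    gauss_expect(function(z) {
      vapply(z, function(zi) 100 * mean(stats::plogis(alpha + delta + zi)), 0)
    }, sd = tau, rule = rule) - fi_mean_target
  }
  delta <- stats::uniroot(f, c(-6, 6))$root
  alpha + delta
}

# Average derivative of expected FI wrt liability (Stein's lemma constant)
liability_gain <- function(alpha, tau, rule = gh_rule()) {
  gauss_expect(function(z) {
    vapply(z, function(zi) {
      p <- stats::plogis(alpha + zi)
      100 * mean(p * (1 - p))
    }, 0)
  }, sd = tau, rule = rule)
}

# block-correlated standard-normal panel, standardized within sample
sim_biomarker_panel <- function(n, p, blocks) {
  z <- matrix(stats::rnorm(n * p), n, p)
  idx <- 1L
  for (b in blocks) {
    size <- as.integer(b[1L]); rho <- b[2L]
    if (idx + size - 1L > p) stopf("biomarker blocks exceed panel size")
    shared <- stats::rnorm(n)
    cols <- idx:(idx + size - 1L)
    z[, cols] <- sqrt(rho) * shared + sqrt(1 - rho) * z[, cols]
    idx <- idx + size
  }
  scale(z)  # mean 0, sample SD 1 within sample
}

#' Simulate a frailty cohort
#'
#' Draws ages, sex, a block-correlated standardized biomarker panel, a
#' binary deficit matrix whose item probabilities are logistic in a single
#' latent liability, and the 5 frailty-phenotype criteria from the same
#' liability.  The liability aggregates the configured biomarker and
#' covariate effects plus residual heterogeneity, scaled so that the
#' population OLS slope of FI (\%) on each biomarker equals its configured
#' effect.  Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return object of class \code{frailty_cohort}: a list with
#'   \code{phenotypes} (data frame: id, age, sex, bmi, biomarker z-scores),
#'   \code{deficits} (individuals x items 0/1 matrix),
#'   \code{fp_criteria} (individuals x 5 logical matrix),
#'   \code{category_map}, and \code{truth} (calibration constants and the
#'   configured effects).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(config) {
  n <- config$n_individuals
  p <- config$n_biomarkers
  age <- stats::rnorm(n, config$age_mean_sd[1L], config$age_mean_sd[2L])
  sex <- stats::rbinom(n, 1L, 0.5)           # 1 = female
  bmi <- stats::rnorm(n, 27.3, 4.7)
  z <- sim_biomarker_panel(n, p, config$biomarker_blocks)
  colnames(z) <- paste0("bm", seq_len(p))

  # liability on the FI% scale, then rescaled by the calibration constant K
  cov_std <- cbind(age = (age - config$age_mean_sd[1L]) / config$age_mean_sd[2L],
                   sex = (sex - 0.5) / 0.5,
                   bmi = (bmi - 27.3) / 4.7)
  ce <- config$covariate_effects
  u <- drop(z %*% config$true_effects)
  for (nm in intersect(names(ce), colnames(cov_std)))
    u <- u + ce[[nm]] * cov_std[, nm]

  # tau: total liability SD consistent with the target FI SD.  The FI
  # variance splits into between-individual variance of the conditional
  # mean plus within-individual Bernoulli noise; tau is solved so their sum
  # matches the target.
  cal <- calibrate_liability(config)
  K <- cal$gain
  var_u <- sum(config$true_effects^2) +
    sum(ce[intersect(names(ce), colnames(cov_std))]^2)
  sigma_extra2 <- cal$tau^2 - var_u / K^2
  if (sigma_extra2 < 0)
    stopf("configured effects imply more FI variance than the target allows; raise fi_target SD")
  eta <- u / K + stats::rnorm(n, 0, sqrt(sigma_extra2))

  probs <- stats::plogis(outer(eta, cal$alpha, `+`))
  deficits <- matrix(stats::rbinom(length(probs), 1L, probs), n,
                     config$n_deficit_items)
  colnames(deficits) <- paste0("item", seq_len(config$n_deficit_items))

  fp_probs <- stats::plogis(cal$alpha_fp + eta)
  fp_criteria <- matrix(stats::rbinom(n * 5L, 1L, rep(fp_probs, 5L)) == 1L, n, 5L)
  colnames(fp_criteria) <- c("weight_loss", "exhaustion", "slowness",
                             "low_activity", "weakness")

  structure(list(
    phenotypes = data.frame(id = seq_len(n), age = age, sex = sex, bmi = bmi, z,
                            check.names = FALSE),
    deficits = deficits,
    fp_criteria = fp_criteria,
    category_map = config$category_map,
    truth = list(true_effects = config$true_effects,
                 covariate_effects = ce,
                 liability = eta, gain = K, tau = cal$tau,
                 item_intercepts = cal$alpha)
  ), class = "frailty_cohort")
}

# Solve for the liability spread tau matching the target FI SD, then the
# item intercepts and gain at that tau.  Deterministic (quadrature only).
calibrate_liability <- function(config) {
  rule <- gh_rule()
  target_mean <- config$fi_target[1L]
  target_sd <- config$fi_target[2L]
  K_items <- config$n_deficit_items
  fi_var_at <- function(tau) {
    alpha <- calibrate_items(K_items, target_mean, tau, rule)
    m1 <- gauss_expect(function(z) vapply(z, function(zi)
      100 * mean(stats::plogis(alpha + zi)), 0), tau, rule)
    m2 <- gauss_expect(function(z) vapply(z, function(zi)
      (100 * mean(stats::plogis(alpha + zi)))^2, 0), tau, rule)
    binom <- gauss_expect(function(z) vapply(z, function(zi) {
      pk <- stats::plogis(alpha + zi)
      (100 / K_items)^2 * sum(pk * (1 - pk))
    }, 0), tau, rule)
    list(var = m2 - m1^2 + binom, alpha = alpha)
  }
  tau <- stats::uniroot(function(t) fi_var_at(t)$var - target_sd^2,
                        c(0.05, 3))$root
  alpha <- fi_var_at(tau)$alpha
  gain <- liability_gain(alpha, tau, rule)
  # FP criterion intercept: mean score = 5 * E[plogis(alpha_fp + eta)]
  ptarget <- config$fp_target_mean / 5
  alpha_fp <- stats::uniroot(function(a)
    gauss_expect(function(z) stats::plogis(a + z), tau, rule) - ptarget,
    c(-10, 5))$root
  list(tau = tau, alpha = alpha, gain = gain, alpha_fp = alpha_fp)
}
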