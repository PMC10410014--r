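#' Simulate a twin cohort for co-twin control analysis
#'
#' Generates MZ and DZ twin pairs in which a latent additive-genetic factor
#' is correlated 1.0 within MZ and 0.5 within DZ pairs, and a
#' shared-environment factor is correlated 1.0 within all pairs.  Under
#' \code{confounding = "genetic"} (or \code{"shared_env"}) the respective
#' factor drives both the biomarker and the FI, so the population-level
#' association exceeds the causal effect while the within-MZ-pair (or
#' within-any-pair) association recovers the direct effect.  The FI is
#' generated linearly on the percent scale (a Gaussian surrogate, not
#' bounded to \[0,100\]) so that population and within-pair OLS estimands
#' are exact.
#'
#' @param config a [cohort_config()]; the first element of
#'   \code{true_effects} is the direct (causal) biomarker effect in FI \%
#'   per SD, and \code{fi_target} locates the FI distribution.
#' @param n_mz_pairs,n_dz_pairs pair counts (each may be 0, but not both).
#' @param confounding one of \code{"none"}, \code{"genetic"},
#'   \code{"shared_env"}.
#' @param confounder_effect effect of the confounding factor on the FI in
#'   \% per SD of the factor (it also loads on the biomarker with weight
#'   0.6 when active).
#' @return a \code{twin_pair_table}: data frame with columns pair_id,
#'   zygosity, twin, age, sex, bmi, biomarker, fi; attribute \code{truth}
#'   stores the generating parameters.
#' @export
simulate_twin_cohort <- function(config, n_mz_pairs, n_dz_pairs,
                                 confounding = c("none", "genetic", "shared_env"),
                                 confounder_effect = 1) {
  stopifnot(inherits(config, "cohort_config"))
  confounding <- match.arg(confounding)
  n_mz_pairs <- as.integer(n_mz_pairs); n_dz_pairs <- as.integer(n_dz_pairs)
  if (n_mz_pairs < 0L || n_dz_pairs < 0L || n_mz_pairs + n_dz_pairs == 0L)
    stopf("configuration error: need a positive number of twin pairs")
  withr::with_seed(config$seed, {
    n_pairs <- n_mz_pairs + n_dz_pairs
    zyg <- rep(c("MZ", "DZ"), c(n_mz_pairs, n_dz_pairs))
    a_shared <- stats::rnorm(n_pairs)
    c_shared <- stats::rnorm(n_pairs)
    # per-twin additive genetic factor: corr 1 within MZ, 0.5 within DZ
    A <- matrix(rep(a_shared, 2L), n_pairs, 2L)
    dz <- zyg == "DZ"
    if (any(dz)) {
      uniq <- matrix(stats::rnorm(2L * sum(dz)), sum(dz), 2L)
      A[dz, ] <- sqrt(0.5) * a_shared[dz] + sqrt(0.5) * uniq
    }
    C <- matrix(rep(c_shared, 2L), n_pairs, 2L)

    theta <- config$true_effects[1L]
    w <- 0.6  # loading of the active confounder on the biomarker
    Fac <- switch(confounding, none = NULL, genetic = A, shared_env = C)
    ex <- matrix(stats::rnorm(2L * n_pairs), n_pairs, 2L)
    x <- if (is.null(Fac)) ex else w * Fac + sqrt(1 - w^2) * ex

    age_pair <- stats::rnorm(n_pairs, config$age_mean_sd[1L], config$age_mean_sd[2L])
    sex_pair <- stats::rbinom(n_pairs, 1L, 0.5)
    bmi <- matrix(stats::rnorm(2L * n_pairs, 25.1, 3.3), n_pairs, 2L)
    ce_age <- config$covariate_effects[["age"]] %||% 0
    age_z <- (age_pair - config$age_mean_sd[1L]) / config$age_mean_sd[2L]

    resid_sd <- max(config$fi_target[2L]^2 - theta^2 -
                      (if (is.null(Fac)) 0 else confounder_effect^2) -
                      ce_age^2, 1) ^ 0.5
    ey <- matrix(stats::rnorm(2L * n_pairs, 0, resid_sd), n_pairs, 2L)
    fi <- config$fi_target[1L] + theta * x + ce_age * age_z + ey
    if (!is.null(Fac)) fi <- fi + confounder_effect * Fac

    out <- data.frame(
      pair_id = rep(seq_len(n_pairs), each = 2L),
      zygosity = rep(zyg, each = 2L),
      twin = rep(1:2, n_pairs),
      age = rep(age_pair, each = 2L),
      sex = rep(sex_pair, each = 2L),
      bmi = as.vector(t(bmi)),
      biomarker = as.vector(t(x)),
      fi = as.vector(t(fi)),
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(theta = theta, confounding = confounding,
                               confounder_effect = confounder_effect,
                               biomarker_loading = w)
    class(out) <- c("twin_pair_table", "data.frame")
    out
  })
}
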