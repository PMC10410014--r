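#' Configuration for paired exposure/outcome GWAS summary statistics
#'
#' Describes a two-sample MR world: per-SNP exposure effects scaled to a
#' given heritability, outcome effects equal to \code{theta} times the
#' exposure effect plus a pleiotropy term, standard errors implied by
#' sample size and allele frequency for standardized traits
#' (se = 1/sqrt(2 EAF (1-EAF) n)), and Wald-consistent p-values.
#'
#' @param n_snps number of SNPs.
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param theta true causal effect (outcome units per SD exposure).
#' @param exposure_h2 fraction of exposure variance explained by the SNPs,
#'   in (0,1).
#' @param pleiotropy_mode one of \code{"none"}, \code{"balanced"},
#'   \code{"directional"}, \code{"outlier"}.
#' @param pleiotropy_mean mean direct (pleiotropic) SNP-outcome effect, in
#'   outcome units; for \code{"balanced"} the mean is 0 and
#'   \code{pleiotropy_sd} sets the spread.
#' @param pleiotropy_sd SD of the pleiotropy term (default 0.02).
#' @param n_outliers number of outlier SNPs for \code{"outlier"} mode.
#' @param outlier_multiplier outliers get a per-SNP ratio of
#'   \code{outlier_multiplier * theta} (default 10).
#' @param inside_violated if TRUE the pleiotropy term is correlated with
#'   instrument strength (violating the InSIDE assumption).
#' @param palindromic_fraction fraction of SNPs given A/T or C/G alleles.
#' @param ld_blocks list of \code{c(size, r2)}: SNPs are laid out in
#'   consecutive blocks with constant pairwise r2 inside each block and 0
#'   between blocks.
#' @param category_mediation named numeric vector: fraction of each SNP's
#'   outcome effect routed through the named deficit category; fractions
#'   must sum to at most 1.
#' @param seed integer seed; mandatory.
#' @return object of class \code{gwas_sim_config}.
#' @export
gwas_sim_config <- function(n_snps,
                            n_exposure = 115078,
                            n_outcome = 164610,
                            theta = 0,
                            exposure_h2 = 0.05,
                            pleiotropy_mode = c("none", "balanced",
                                                "directional", "outlier"),
                            pleiotropy_mean = 0,
                            pleiotropy_sd = 0.02,
                            n_outliers = 0L,
                            outlier_multiplier = 10,
                            inside_violated = FALSE,
                            palindromic_fraction = 0,
                            ld_blocks = list(),
                            category_mediation = numeric(),
                            seed) {
  if (missing(seed)) stopf("seed is mandatory for synthetic data")
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (!is.finite(theta)) stopf("theta must be finite")
  if (exposure_h2 <= 0 || exposure_h2 >= 1) stopf("exposure_h2 must lie in (0,1)")
  if (palindromic_fraction < 0 || palindromic_fraction > 1)
    stopf("palindromic_fraction must lie in [0,1]")
  if (n_outliers > n_snps) stopf("configuration error: n_outliers > n_snps")
  if (length(category_mediation) &&
      (any(category_mediation < 0) || sum(category_mediation) > 1))
    stopf("category_mediation fractions must be in [0,1] and sum to at most 1")
  structure(list(
    n_snps = as.integer(n_snps), n_exposure = n_exposure, n_outcome = n_outcome,
    theta = theta, exposure_h2 = exposure_h2,
    pleiotropy_mode = pleiotropy_mode, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, n_outliers = as.integer(n_outliers),
    outlier_multiplier = outlier_multiplier,
    inside_violated = isTRUE(inside_violated),
    palindromic_fraction = palindromic_fraction,
    ld_blocks = ld_blocks, category_mediation = category_mediation,
    seed = as.integer(seed)
  ), class = "gwas_sim_config")
}

summary_stats_columns <- c("variant_id", "chromosome", "base_pair_location",
                           "effect_allele", "other_allele",
                           "effect_allele_frequency", "beta",
                           "standard_error", "p_value", "n")

make_summary_stats <- function(id, chr, pos, ea, oa, eaf, beta, se, n) {
  data.frame(variant_id = id, chromosome = chr, base_pair_location = pos,
             effect_allele = ea, other_allele = oa,
             effect_allele_frequency = eaf, beta = beta, standard_error = se,
             p_value = 2 * stats::pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

#' Simulate a paired exposure/outcome GWAS
#'
#' Draws per-SNP exposure effects scaled so the instruments explain
#' \code{exposure_h2} of a standardized exposure; outcome effects are
#' \code{theta} times the exposure effect plus a pleiotropy term drawn
#' according to \code{pleiotropy_mode}; observed betas add sampling noise
#' with se = 1/sqrt(2 EAF (1-EAF) n) and Wald p-values are exact.  When
#' \code{category_mediation} routes part of the causal effect through
#' deficit categories, outcome summary statistics for each of the 11
#' category-stripped FIs are also emitted (the stripped outcome loses the
#' mediated component for its own category).
#'
#' @param config a [gwas_sim_config()].
#' @return object of class \code{gwas_sim}: list with \code{exposure} and
#'   \code{outcome} summary-statistics data frames (GWAS-SSF-like columns),
#'   \code{outcome_stripped} (named list, present when mediation is
#'   configured), \code{ld} (data frame snp_a/snp_b/r2 for within-block
#'   pairs), and \code{truth} (theta, per-SNP gamma and alpha, outlier
#'   ids, mediation fractions).
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "gwas_sim_config"))
  withr::with_seed(config$seed, simulate_gwas_pair_impl(config))
}

simulate_gwas_pair_impl <- function(config) {
  J <- config$n_snps
  eaf <- stats::runif(J, 0.05, 0.95)

  # allele coding: a configured fraction is strand-ambiguous (A/T or C/G)
  pal <- stats::runif(J) < config$palindromic_fraction
  pal_pairs <- rbind(c("A", "T"), c("C", "G"))
  oth_pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
  ea <- oa <- character(J)
  pick_p <- sample(1:2, J, replace = TRUE)
  pick_o <- sample(1:4, J, replace = TRUE)
  ea[pal] <- pal_pairs[pick_p[pal], 1L]; oa[pal] <- pal_pairs[pick_p[pal], 2L]
  ea[!pal] <- oth_pairs[pick_o[!pal], 1L]; oa[!pal] <- oth_pairs[pick_o[!pal], 2L]

  # genomic layout: LD blocks first, remaining SNPs independent
  block_id <- integer(J); block_r2 <- numeric(J)
  idx <- 1L; bid <- 0L
  for (b in config$ld_blocks) {
    bid <- bid + 1L
    size <- as.integer(b[1L])
    if (idx + size - 1L > J) stopf("ld_blocks exceed n_snps")
    block_id[idx:(idx + size - 1L)] <- bid
    block_r2[idx:(idx + size - 1L)] <- b[2L]
    idx <- idx + size
  }
  singles <- block_id == 0L
  block_id[singles] <- bid + seq_len(sum(singles))
  chr <- ((block_id - 1L) %% 22L) + 1L
  pos <- 1e6 * ((block_id - 1L) %/% 22L + 1L) + stats::ave(
    rep(1, J), block_id, FUN = seq_along) * 1000
  pos <- as.integer(pos)

  # true per-SNP exposure effects scaled to exposure_h2 (standardized trait)
  gamma <- stats::rnorm(J)
  v <- 2 * eaf * (1 - eaf)
  gamma <- gamma * sqrt(config$exposure_h2 / sum(v * gamma^2))

  alpha <- numeric(J)
  outlier_ids <- character(0)
  mode <- config$pleiotropy_mode
  if (mode == "balanced") {
    alpha <- stats::rnorm(J, 0, config$pleiotropy_sd)
  } else if (mode == "directional") {
    # directional pleiotropy is defined in the exposure-increasing allele
    # orientation (otherwise allele-coding sign flips would symmetrize it
    # and no estimator could see a direction)
    alpha <- stats::rnorm(J, config$pleiotropy_mean, config$pleiotropy_sd) *
      sign(gamma)
  } else if (mode == "outlier") {
    out_idx <- sample.int(J, config$n_outliers)
    target_ratio <- if (config$theta != 0) {
      config$outlier_multiplier * config$theta
    } else {
      config$outlier_multiplier * stats::sd(gamma)
    }
    alpha[out_idx] <- (target_ratio - config$theta) * gamma[out_idx]
    outlier_ids <- paste0("rs", out_idx)
  }
  if (config$inside_violated && mode != "none")
    alpha <- alpha + 2 * config$pleiotropy_sd * gamma / stats::sd(gamma)

  med <- config$category_mediation
  beta_y_true <- config$theta * gamma + alpha

  se_x <- 1 / sqrt(v * config$n_exposure)
  se_y <- 1 / sqrt(v * config$n_outcome)
  bx <- gamma + stats::rnorm(J, 0, se_x)
  by <- beta_y_true + stats::rnorm(J, 0, se_y)
  ids <- paste0("rs", seq_len(J))

  exposure <- make_summary_stats(ids, chr, pos, ea, oa, eaf, bx, se_x,
                                 config$n_exposure)
  outcome <- make_summary_stats(ids, chr, pos, ea, oa, eaf, by, se_y,
                                config$n_outcome)

  outcome_stripped <- NULL
  if (length(med)) {
    cats <- default_category_map(49L)
    outcome_stripped <- lapply(unique(cats), function(ct) {
      frac <- if (ct %in% names(med)) med[[ct]] else 0
      b_true <- (config$theta * (1 - frac)) * gamma + alpha
      make_summary_stats(ids, chr, pos, ea, oa, eaf,
                         b_true + stats::rnorm(J, 0, se_y), se_y,
                         config$n_outcome)
    })
    names(outcome_stripped) <- unique(cats)
  }

  # pairwise LD records for within-block pairs
  ld <- NULL
  in_block <- which(block_r2 > 0)
  if (length(in_block)) {
    combs <- do.call(rbind, lapply(unique(block_id[in_block]), function(b) {
      snps <- ids[block_id == b & block_r2 > 0]
      if (length(snps) < 2L) return(NULL)
      cmb <- utils::combn(snps, 2L)
      data.frame(snp_a = cmb[1L, ], snp_b = cmb[2L, ],
                 r2 = block_r2[match(snps[1L], ids)],
                 stringsAsFactors = FALSE)
    }))
    ld <- combs
  }
  if (is.null(ld))
    ld <- data.frame(snp_a = character(0), snp_b = character(0),
                     r2 = numeric(0), stringsAsFactors = FALSE)

  structure(list(
    exposure = exposure, outcome = outcome,
    outcome_stripped = outcome_stripped, ld = ld,
    truth = list(theta = config$theta, gamma = gamma, alpha = alpha,
                 outlier_ids = outlier_ids, mediation = med,
                 exposure_h2 = config$exposure_h2)
  ), class = "gwas_sim")
}
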