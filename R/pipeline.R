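#' Pipeline configuration
#'
#' Bundles every threshold, size and seed of the discovery -> selection ->
#' replication -> MR -> co-twin workflow.  Defaults carry the canonical
#' analysis constants: Bonferroni alpha 0.05 over a 200-biomarker family,
#' replication alpha 0.05, genome-wide significance 5e-8, clumping r2
#' 0.001 within 10,000 kb, palindromic MAF 0.42, FDR q 0.05.
#'
#' @param n_discovery,n_replication sample sizes for the synthetic
#'   discovery cohort and each of the two replication cohorts.
#' @param n_biomarkers biomarker panel size.
#' @param true_effects biomarker effects on the FI (\% per SD).
#' @param biomarker_blocks correlated-block structure, see
#'   [cohort_config()].
#' @param bonferroni_alpha,bonferroni_family Bonferroni family-wise level
#'   and family size (0.05 and 200 give the 0.00025 threshold).
#' @param replication_alpha meta-analysis replication level.
#' @param gwas_p,clump_r2,clump_window_kb,palindromic_maf,fdr_q MR
#'   thresholds.
#' @param mr_n_snps SNPs simulated per exposure GWAS.
#' @param mr_methods estimators run in the battery.
#' @param n_boot,n_sim bootstrap/simulation sizes for the battery.
#' @param unavailable_biomarkers biomarker ids treated as unavailable in
#'   the replication cohorts (carried to MR flagged "unavailable").
#' @param twin_confounding,twin_confounder_effect co-twin generating mode.
#' @param n_mz_pairs,n_dz_pairs twin-pair counts.
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(n_discovery = 5000L, n_replication = 2000L,
                            n_biomarkers = 20L,
                            true_effects = NULL,
                            biomarker_blocks = list(),
                            bonferroni_alpha = 0.05,
                            bonferroni_family = 200L,
                            replication_alpha = 0.05,
                            gwas_p = 5e-8, clump_r2 = 0.001,
                            clump_window_kb = 10000,
                            palindromic_maf = 0.42, fdr_q = 0.05,
                            mr_n_snps = 120L,
                            mr_methods = c("ivw", "egger",
                                           "weighted_median",
                                           "weighted_mode"),
                            n_boot = 200L, n_sim = 500L,
                            unavailable_biomarkers = character(),
                            twin_confounding = "none",
                            twin_confounder_effect = 1,
                            n_mz_pairs = 1132L, n_dz_pairs = 2762L,
                            seed) {
  if (missing(seed)) stopf("seed is mandatory")
  if (is.null(true_effects)) {
    true_effects <- numeric(n_biomarkers)
    true_effects[seq_len(min(3L, n_biomarkers))] <- c(1.5, 1.0, -0.8)[
      seq_len(min(3L, n_biomarkers))]
  }
  stopifnot(bonferroni_alpha > 0, gwas_p > 0, fdr_q > 0)
  structure(as.list(environment()), class = "pipeline_config")
}

# derived per-stage seeds, kept below 2^31
stage_seed <- function(seed, k)
  as.integer((as.numeric(seed) * 101 + as.numeric(k) * 7919) %% 2000000000)

#' Run the full synthetic discovery-to-co-twin pipeline
#'
#' Executes, in order: cohort simulation and frailty-score construction;
#' the Bonferroni-controlled discovery screen; LASSO selection; forwarding
#' of biomarkers that pass both filters; replication in two simulated
#' cohorts pooled by DerSimonian-Laird meta-analysis; the two-sample MR
#' battery (with BH-FDR across the primary IVW family) on biomarkers that
#' replicated or were unavailable; and the co-twin control analysis.
#' Every stage seed and threshold is recorded in the run log; reruns with
#' the same config are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, per-stage results TSVs
#'   and \code{run_log.txt} are written there.
#' @return object of class \code{frailty_pipeline}: list with
#'   \code{screen}, \code{lasso}, \code{forwarded}, \code{meta},
#'   \code{mr}, \code{cotwin}, \code{summary} (observational beta, meta
#'   beta, IVW beta and flags per biomarker) and \code{log}.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- c(sprintf("master seed: %d", config$seed),
           sprintf("bonferroni: alpha=%g family=%d threshold=%g",
                   config$bonferroni_alpha, config$bonferroni_family,
                   bonferroni_threshold(config$bonferroni_family,
                                        config$bonferroni_alpha)),
           sprintf("gwas_p=%g clump_r2=%g window_kb=%g palindromic_maf=%g fdr_q=%g",
                   config$gwas_p, config$clump_r2, config$clump_window_kb,
                   config$palindromic_maf, config$fdr_q))

  ## discovery cohort, frailty scores, screen
  cc <- cohort_config(config$n_discovery, config$n_biomarkers,
                      biomarker_blocks = config$biomarker_blocks,
                      true_effects = config$true_effects,
                      seed = stage_seed(config$seed, 1L))
  cohort <- simulate_cohort(cc)
  fi <- compute_fi(cohort$deficits)
  bm <- paste0("bm", seq_len(config$n_biomarkers))
  disc <- cbind(cohort$phenotypes, fi = fi$fi)
  screen <- run_screen(disc, outcome = "fi", biomarkers = bm,
                       covariates = c("age", "sex"),
                       alpha = config$bonferroni_alpha,
                       family_size = config$bonferroni_family)
  log <- c(log, sprintf("discovery screen: %d biomarkers, %d flagged",
                        length(bm), sum(screen$flag)))

  ## LASSO selection (age and sex mandatory, unpenalized)
  lasso <- lasso_select(as.matrix(disc[bm]), disc$fi,
                        mandatory = cbind(age = disc$age, sex = disc$sex),
                        seed = stage_seed(config$seed, 2L))
  forwarded <- intersect(screen$id[screen$flag], lasso$selected)
  log <- c(log, sprintf("forwarded to replication (Bonferroni & LASSO): %d",
                        length(forwarded)))

  ## replication in two cohorts + DL meta-analysis
  meta_rows <- list()
  rep_cohorts <- lapply(1:2, function(r) {
    rcc <- cohort_config(config$n_replication, config$n_biomarkers,
                         biomarker_blocks = config$biomarker_blocks,
                         true_effects = config$true_effects,
                         seed = stage_seed(config$seed, 2L + r))
    co <- simulate_cohort(rcc)
    cbind(co$phenotypes, fi = compute_fi(co$deficits)$fi)
  })
  available <- setdiff(forwarded, config$unavailable_biomarkers)
  for (b in available) {
    ests <- lapply(rep_cohorts, function(d)
      fit_linear_assoc(d$fi, d[[b]], covariates = d[c("age", "sex")], id = b,
                       model = "replication"))
    m <- dl_meta(vapply(ests, `[[`, 0, "beta"), vapply(ests, `[[`, 0, "se"),
                 alpha = config$replication_alpha)
    meta_rows[[b]] <- data.frame(
      id = b, beta = m$beta, se = m$se, ci_low = m$ci_low,
      ci_high = m$ci_high, p = m$p, tau2 = m$tau2, Q = m$Q, k = m$k,
      replicated = m$replicated, stringsAsFactors = FALSE)
  }
  meta <- if (length(meta_rows)) do.call(rbind, meta_rows) else NULL
  replicated <- if (is.null(meta)) character(0) else meta$id[meta$replicated]
  to_mr <- c(replicated, intersect(forwarded, config$unavailable_biomarkers))
  log <- c(log, sprintf("replicated: %d; unavailable carried to MR: %d",
                        length(replicated),
                        length(intersect(forwarded,
                                         config$unavailable_biomarkers))))

  ## MR battery: one synthetic exposure/outcome pair per biomarker
  mr <- NULL
  if (length(to_mr)) {
    true_map <- stats::setNames(config$true_effects, bm)
    exposures <- list(); outcomes_fi <- list(); outcomes_fp <- list()
    for (i in seq_along(to_mr)) {
      b <- to_mr[i]
      gc_fi <- gwas_sim_config(config$mr_n_snps, theta = true_map[[b]],
                               seed = stage_seed(config$seed, 10L + i))
      sim_fi <- simulate_gwas_pair(gc_fi)
      gc_fp <- gwas_sim_config(config$mr_n_snps, theta = 0,
                               seed = stage_seed(config$seed, 400L + i))
      sim_fp <- simulate_gwas_pair(gc_fp)
      exposures[[b]] <- list(summary_stats = sim_fi$exposure, ld = sim_fi$ld)
      outcomes_fi[[b]] <- sim_fi$outcome
      outcomes_fp[[b]] <- sim_fp$outcome
    }
    # each exposure has its own simulated outcome pair; run per-exposure
    rows <- list(); fits <- list()
    for (b in to_mr) {
      bt <- run_mr_battery(exposures[b],
                           outcomes = list(FI = outcomes_fi[[b]],
                                           FP = outcomes_fp[[b]]),
                           methods = config$mr_methods,
                           p_threshold = config$gwas_p,
                           r2_threshold = config$clump_r2,
                           window_kb = config$clump_window_kb,
                           palindromic_maf = config$palindromic_maf,
                           fdr_q = config$fdr_q,
                           n_boot = config$n_boot, n_sim = config$n_sim,
                           seed = stage_seed(config$seed, 20L))
      rows[[b]] <- as.data.frame(bt)
    }
    mr <- do.call(rbind, rows)
    rownames(mr) <- NULL
    # FDR across the pooled primary IVW family (biomarkers x {FI, FP})
    primary <- mr$method == "IVW" & mr$outcome %in% c("FI", "FP")
    fdr <- bh_fdr(mr$p[primary], config$fdr_q)
    mr$fdr_q[primary] <- fdr$adjusted
    attr(mr, "fdr_family_size") <- sum(primary)
    attr(mr, "fdr_threshold") <- fdr$threshold
    log <- c(log, sprintf("MR FDR family size: %d (%d exposures x 2 outcomes)",
                          sum(primary), length(to_mr)))
  }

  ## co-twin control on the first effect biomarker
  twin_cc <- cohort_config(2L, config$n_biomarkers,
                           true_effects = config$true_effects,
                           seed = stage_seed(config$seed, 30L))
  twins <- simulate_twin_cohort(twin_cc, config$n_mz_pairs,
                                config$n_dz_pairs,
                                confounding = config$twin_confounding,
                                confounder_effect = config$twin_confounder_effect)
  pop <- fit_linear_assoc(twins$fi, twins$biomarker,
                          covariates = twins[c("age", "sex")],
                          cluster_ids = twins$pair_id, id = "biomarker",
                          model = "population")
  dz <- within_pair_estimate(twins, "DZ", covariates = c("bmi"))
  mz <- within_pair_estimate(twins, "MZ", covariates = c("bmi"))
  cotwin <- cotwin_compare(pop, dz, mz)
  log <- c(log, sprintf("co-twin: pop=%.3f dz=%.3f mz=%.3f label=%s",
                        pop$beta, dz$beta, mz$beta, cotwin$label))

  ## summary table: observational beta, meta beta, IVW beta, flags
  summary_tab <- data.frame(id = bm, stringsAsFactors = FALSE)
  summary_tab$obs_beta <- screen$beta[match(bm, screen$id)]
  summary_tab$bonferroni_flag <- screen$flag[match(bm, screen$id)]
  summary_tab$lasso_selected <- bm %in% lasso$selected
  summary_tab$meta_beta <- if (is.null(meta)) NA_real_ else
    meta$beta[match(bm, meta$id)]
  summary_tab$replicated <- if (is.null(meta)) FALSE else
    bm %in% meta$id[meta$replicated]
  summary_tab$unavailable <- bm %in%
    intersect(forwarded, config$unavailable_biomarkers)
  ivw_fi <- if (is.null(mr)) NULL else
    mr[mr$method == "IVW" & mr$outcome == "FI", ]
  summary_tab$ivw_beta <- if (is.null(ivw_fi)) NA_real_ else
    ivw_fi$beta[match(bm, ivw_fi$exposure)]

  out <- structure(list(
    config = config, screen = screen, lasso = lasso, forwarded = forwarded,
    meta = meta, mr = mr, cotwin = cotwin, summary = summary_tab,
    log = log
  ), class = "frailty_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(screen, file.path(out_dir, "screen.tsv"))
    if (!is.null(meta)) write_results(meta, file.path(out_dir, "meta.tsv"))
    if (!is.null(mr)) write_results(mr, file.path(out_dir, "mr.tsv"))
    write_results(summary_tab, file.path(out_dir, "summary.tsv"))
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  out
}

#' @export
print.frailty_pipeline <- function(x, ...) {
  cat("Metabolite-frailty pipeline run\n")
  for (l in x$log) cat(" ", l, "\n")
  invisible(x)
}
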