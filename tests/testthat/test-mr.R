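ss_row <- function(id, chr, pos, ea, oa, eaf, beta, se, n = 1e5) {
  data.frame(variant_id = id, chromosome = chr, base_pair_location = pos,
             effect_allele = ea, other_allele = oa,
             effect_allele_frequency = eaf, beta = beta, standard_error = se,
             p_value = 2 * pnorm(-abs(beta / se)), n = n,
             stringsAsFactors = FALSE)
}

test_that("instrument selection applies the significance filter and greedy clumping", {
  ex <- rbind(
    ss_row("rs1", 1, 1e6, "A", "G", .3, .10, .010),
    ss_row("rs2", 1, 1.005e6, "A", "G", .3, .08, .010),
    ss_row("rs3", 2, 5e6, "A", "G", .3, .12, .010))
  ex$p_value <- c(1e-9, 1e-7, 1e-10)
  expect_equal(sum(ex$p_value < 5e-8), 2L)
  # 5 kb apart, r2 = 0.5: only the lower-p SNP of the pair survives
  ex2 <- ex; ex2$p_value <- c(1e-9, 1e-12, 1e-10)
  ld <- data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5)
  expect_setequal(select_instruments(ex2, ld = ld), c("rs2", "rs3"))
  # independent SNPs all pass
  expect_setequal(select_instruments(ex2, ld = NULL), c("rs1", "rs2", "rs3"))
  expect_warning(out <- select_instruments(ss_row("rs9", 1, 1, "A", "G", .3, .001, .01)),
                 "no SNP passes")
  expect_length(out, 0L)
})

test_that("harmonization aligns alleles, flips swapped codings, drops high-MAF palindromes", {
  ex <- rbind(ss_row("rs1", 1, 100, "A", "G", .3, .10, .01),
              ss_row("rs2", 1, 2e6, "A", "G", .25, .10, .01),
              ss_row("rs3", 1, 4e6, "A", "T", .45, .10, .01),
              ss_row("rs4", 1, 6e6, "A", "T", .10, .10, .01),
              ss_row("rs5", 1, 8e6, "C", "G", .3, .10, .01))
  out <- rbind(ss_row("rs1", 1, 100, "A", "G", .3, .05, .01),
               ss_row("rs2", 1, 2e6, "G", "A", .75, .05, .01),  # swapped coding
               ss_row("rs3", 1, 4e6, "A", "T", .45, .05, .01),  # palindromic MAF .45
               ss_row("rs4", 1, 6e6, "A", "T", .12, .05, .01),  # palindromic, frequency-aligned
               ss_row("rs6", 1, 8e6, "C", "G", .3, .05, .01))   # rs5 missing from outcome
  h <- harmonize(ex, out, ex$variant_id)
  expect_setequal(h$variant_id, c("rs1", "rs2", "rs4"))
  expect_equal(h$beta_outcome[h$variant_id == "rs1"], 0.05)
  expect_equal(h$beta_outcome[h$variant_id == "rs2"], -0.05)   # swap rule
  expect_equal(h$beta_outcome[h$variant_id == "rs4"], 0.05)    # freqs agree: no flip
  drops <- attr(h, "dropped")
  expect_equal(drops$reason[drops$variant_id == "rs3"], "dropped_palindromic")
  expect_equal(drops$reason[drops$variant_id == "rs5"], "dropped_missing")
  expect_equal(h$ratio, h$beta_outcome / h$beta_exposure)
})

test_that("harmonization is involutive and invariant to flipping both codings", {
  g <- simulate_gwas_pair(gwas_sim_config(60, theta = 0.2,
                                          palindromic_fraction = 0.2, seed = 14))
  iv <- g$exposure$variant_id
  h1 <- harmonize(g$exposure, g$outcome, iv)
  # rebuild an outcome from the harmonized set and harmonize again
  out2 <- g$outcome
  m <- match(h1$variant_id, out2$variant_id)
  out2 <- out2[m, ]
  out2$effect_allele <- g$exposure$effect_allele[match(h1$variant_id, g$exposure$variant_id)]
  out2$other_allele <- g$exposure$other_allele[match(h1$variant_id, g$exposure$variant_id)]
  out2$beta <- h1$beta_outcome
  out2$effect_allele_frequency <- h1$eaf_exposure
  h2 <- harmonize(g$exposure, out2, h1$variant_id)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$ratio, h1$ratio)
  # flip BOTH studies' allele coding: estimates unchanged
  flip_ss <- function(ss) {
    tmp <- ss$effect_allele
    ss$effect_allele <- ss$other_allele; ss$other_allele <- tmp
    ss$effect_allele_frequency <- 1 - ss$effect_allele_frequency
    ss$beta <- -ss$beta
    ss
  }
  h3 <- harmonize(flip_ss(g$exposure), flip_ss(g$outcome), iv)
  expect_setequal(h3$variant_id, h1$variant_id)
  m3 <- match(h1$variant_id, h3$variant_id)
  expect_equal(h3$ratio[m3], h1$ratio)
  expect_equal(mr_ivw(h3)$beta, mr_ivw(h1)$beta, tolerance = 1e-12)
})

test_that("F-statistics: arithmetic and the genome-wide-threshold value", {
  set <- make_set(c(0.1, 0.05), c(0.01, 0.01), c(0, 0), c(1, 1))
  f <- f_statistic(set)
  expect_equal(unname(f$f[1]), 100)
  # a SNP exactly at Wald p = 5e-8 has F equal to the chi-square quantile
  z <- qnorm(1 - 2.5e-8)
  set2 <- make_set(z * 0.01, 0.01, 0, 1)
  expect_equal(f_statistic(set2)$min_f, qchisq(1 - 5e-8, 1), tolerance = 1e-6)
  expect_equal(qchisq(1 - 5e-8, 1), 29.72, tolerance = 0.01)
})

test_that("IVW matches the hand-computed weighted regression through the origin", {
  set <- make_set(c(1, 1), c(.05, .05), c(0.2, 0.4), c(0.1, 0.1))
  iv <- mr_ivw(set)
  expect_equal(iv$beta, 0.3)
  expect_equal(iv$Q, 2)
  expect_equal(iv$se, 0.1)   # 0.0707... * sqrt(2)
  expect_error(mr_ivw(set[1, ]), "at least 2")
  expect_equal(mr_wald_ratio(set[1, ])$beta, 0.2)
  # multiplicative random-effects floor: no deflation under underdispersion
  set2 <- make_set(c(1, 1, 1), rep(.05, 3), c(0.2, 0.2, 0.2), rep(0.1, 3))
  expect_equal(mr_ivw(set2)$se, 1 / sqrt(300))
})

test_that("all estimators agree on a common ratio; Egger intercept vanishes", {
  set <- make_set(c(0.5, -0.3, 0.8, 0.2), rep(.01, 4),
                  0.4 * c(0.5, -0.3, 0.8, 0.2), c(.05, .04, .06, .05))
  expect_equal(mr_ivw(set)$beta, 0.4, tolerance = 1e-12)
  expect_equal(mr_ivw(set)$Q, 0, tolerance = 1e-20)
  eg <- mr_egger(set)
  expect_equal(eg$beta, 0.4, tolerance = 1e-10)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-10)
  expect_equal(mr_weighted_median(set, n_boot = 50, seed = 1)$beta, 0.4)
  expect_equal(mr_weighted_mode(set, n_boot = 50, seed = 1)$beta, 0.4)
  q <- cochran_q(set, 0.4)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
})

test_that("weighted median interpolates the inverse-variance percentiles", {
  set <- make_set(rep(1, 3), rep(.01, 3), c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(mr_weighted_median(set, n_boot = 20, seed = 2)$beta, 0.2)
  expect_error(mr_weighted_median(set[1:2, ], seed = 1), "at least 3")
})

test_that("weighted mode finds the dominant ratio cluster", {
  set <- make_set(rep(1, 4), rep(.01, 4), c(0.1, 0.1, 0.1, 0.5), rep(0.1, 4))
  est <- mr_weighted_mode(set, phi = 0.3, n_boot = 20, seed = 3)
  expect_lt(abs(est$beta - 0.1), 0.02)
  # degenerate: identical ratios return the common ratio
  set2 <- make_set(rep(1, 3), rep(.01, 3), rep(0.25, 3), rep(0.1, 3))
  expect_equal(mr_weighted_mode(set2, n_boot = 20, seed = 4)$beta, 0.25)
})

test_that("MR-Egger recovers directional pleiotropy and needs 3 SNPs", {
  expect_error(mr_egger(make_set(c(1, 1), c(.1, .1), c(0, 0), c(.1, .1))),
               "at least 3")
  g <- simulate_gwas_pair(gwas_sim_config(100, theta = 0.3,
                                          pleiotropy_mode = "directional",
                                          pleiotropy_mean = 0.05, seed = 15))
  # instruments are selected at genome-wide significance before Egger, as
  # in the analysis pipeline (weak SNPs would make the bX >= 0 orientation
  # unreliable)
  iv <- select_instruments(g$exposure)
  h <- harmonize(g$exposure, g$outcome, iv)
  eg <- mr_egger(h)
  expect_lt(abs(eg$egger_intercept - 0.05), 2 * eg$intercept_se)
})

test_that("MR-PRESSO flags a planted outlier and leaves clean sets alone", {
  expect_error(mr_presso(make_set(rep(1, 3), rep(.1, 3), rep(0, 3), rep(.1, 3)),
                         seed = 1), "at least 4")
  g <- simulate_gwas_pair(gwas_sim_config(30, theta = 0.3, seed = 16))
  h <- harmonize(g$exposure, g$outcome, g$exposure$variant_id)
  # plant one outlier: ratio 10x theta with small ratio SE
  h$beta_outcome[5] <- 10 * 0.3 * h$beta_exposure[5]
  # n_sim must exceed J/outlier_alpha for the Bonferroni-corrected
  # empirical p to be able to fall below the flagging threshold
  pr <- mr_presso(h, n_sim = 1000, seed = 17)
  expect_true(h$variant_id[5] %in% pr$outlier_ids)
  expect_lt(abs(pr$corrected$beta - 0.3), 3 * pr$corrected$se)
  # clean set: no outliers, corrected equals raw
  h2 <- harmonize(g$exposure, g$outcome, g$exposure$variant_id)
  pr2 <- mr_presso(h2, n_sim = 500, seed = 18)
  expect_length(pr2$outlier_ids, 0L)
  expect_equal(pr2$corrected$beta, pr2$raw$beta)
})

test_that("Cochran's Q for the two-SNP example", {
  set <- make_set(c(1, 1), c(.05, .05), c(0.2, 0.4), c(0.1, 0.1))
  q <- cochran_q(set, 0.3)
  expect_equal(q$Q, 2)
  expect_equal(q$df, 1L)
  expect_equal(q$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(round(q$p, 3), 0.157)
})

test_that("BH step-up matches the brute-force oracle and reports the data threshold", {
  r <- bh_fdr(c(0.001, 0.01, 0.03, 0.04, 0.2), q = 0.05)
  expect_equal(sum(r$reject), 4L)
  expect_equal(r$threshold, 0.04)
  expect_true(all(bh_fdr(rep(0.001, 98))$reject))
  r0 <- bh_fdr(rep(1, 5))
  expect_false(any(r0$reject))
  expect_true(is.na(r0$threshold))
  set.seed(20)
  for (m in 1:5) {
    for (rep in 1:40) {
      p <- round(runif(m), 2)   # ties included
      got <- bh_fdr(p, q = 0.05)$reject
      expect_identical(got, bh_brute(p, 0.05))
    }
  }
})

test_that("pleiotropy pruning removes cross-associated instruments", {
  other <- list(glyca = ss_row("rs1", 1, 1, "A", "G", .3, .5, .01),
                ldl = ss_row("rs9", 1, 9, "A", "G", .3, .001, .01))
  pr <- prune_pleiotropic(c("rs1", "rs2"), other)
  expect_equal(pr$kept, "rs2")
  expect_equal(pr$removed$exposure, "glyca")
  expect_equal(prune_pleiotropic(c("rs2", "rs3"), other)$kept, c("rs2", "rs3"))
  expect_warning(out <- prune_pleiotropic("rs1", other), "highly reduced")
  expect_length(out$kept, 0L)
})

test_that("estimator point estimates are invariant to SNP order", {
  g <- simulate_gwas_pair(gwas_sim_config(40, theta = 0.25,
                                          pleiotropy_mode = "balanced", seed = 19))
  h <- harmonize(g$exposure, g$outcome, g$exposure$variant_id)
  p <- withr::with_seed(1, sample(nrow(h)))
  hp <- h[p, ]
  expect_equal(mr_ivw(hp)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(hp)$beta, mr_egger(h)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(hp, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(h, n_boot = 10, seed = 1)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_mode(hp, n_boot = 10, seed = 1)$beta,
               mr_weighted_mode(h, n_boot = 10, seed = 1)$beta, tolerance = 1e-12)
})

test_that("single-instrument exposures fall back to the labeled Wald ratio in mr_fit", {
  set <- make_set(0.1, 0.01, 0.05, 0.02)
  fit <- mr_fit(set, seed = 1)
  expect_equal(names(fit$estimates), "wald_ratio")
  expect_equal(fit$estimates$wald_ratio$method, "Wald_ratio")
  expect_equal(fit$estimates$wald_ratio$beta, 0.5)
  expect_equal(fit$estimates$wald_ratio$se, 0.02 / 0.1)
})
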