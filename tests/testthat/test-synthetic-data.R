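test_that("cohort simulation honors the dimension contract", {
  cc <- cohort_config(1000, 10, seed = 1)
  co <- simulate_cohort(cc)
  expect_equal(nrow(co$phenotypes), 1000L)
  expect_length(grep("^bm[0-9]+$", names(co$phenotypes)), 10L)
  expect_equal(dim(co$deficits), c(1000L, 49L))
  expect_equal(dim(co$fp_criteria), c(1000L, 5L))
  expect_length(unique(co$category_map), 11L)
})

test_that("simulation is deterministic given the seed and seeds are mandatory", {
  cc <- cohort_config(200, 5, seed = 9)
  expect_identical(simulate_cohort(cc), simulate_cohort(cc))
  expect_error(cohort_config(10, 2), "seed is mandatory")
  expect_error(gwas_sim_config(10), "seed is mandatory")
  g <- gwas_sim_config(50, theta = 0.1, seed = 3)
  expect_identical(simulate_gwas_pair(g), simulate_gwas_pair(g))
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(0, 5, seed = 1), "non-positive")
  expect_error(cohort_config(10, 5, biomarker_blocks = list(c(3, 1)), seed = 1),
               "\\[0,1\\)")
  expect_error(gwas_sim_config(10, exposure_h2 = 1.2, seed = 1), "exposure_h2")
  expect_error(gwas_sim_config(10, n_outliers = 11, seed = 1), "n_outliers")
  expect_error(simulate_twin_cohort(cohort_config(2, 1, seed = 1), 0, 0),
               "positive number of twin pairs")
})

test_that("simulated FI distribution tracks the configured cohort profile", {
  cc <- cohort_config(20000, 5, seed = 11)
  co <- simulate_cohort(cc)
  fi <- compute_fi(co$deficits)$fi
  expect_gt(mean(fi), 10); expect_lt(mean(fi), 15)
  expect_gt(sd(fi), 5.5);  expect_lt(sd(fi), 9.5)
  # right skew: mean above median
  expect_gt(mean(fi), median(fi))
  fp <- compute_fp(co$fp_criteria)
  expect_gt(mean(fp), 0.3); expect_lt(mean(fp), 0.9)
})

test_that("screening recovers a configured biomarker effect (OLS oracle)", {
  cc <- cohort_config(20000, 5, true_effects = c(1.5, 0, 0, 0, 0), seed = 2)
  co <- simulate_cohort(cc)
  d <- cbind(co$phenotypes, fi = compute_fi(co$deficits)$fi)
  # closed-form OLS oracle on the generated table
  X <- cbind(1, d$bm1, d$age, d$sex)
  b <- solve(crossprod(X), crossprod(X, d$fi))
  res <- fit_linear_assoc(d$fi, d$bm1, d[c("age", "sex")], id = "bm1")
  expect_equal(res$beta, b[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_lt(abs(res$beta - 1.5), 3 * res$se)
})

test_that("GWAS pair satisfies the Wald relation and frequency bounds exactly", {
  g <- simulate_gwas_pair(gwas_sim_config(300, theta = 0.2,
                                          palindromic_fraction = 0.3, seed = 5))
  for (ss in list(g$exposure, g$outcome)) {
    expect_true(all(ss$effect_allele_frequency > 0 &
                      ss$effect_allele_frequency < 1))
    expect_equal(ss$p_value,
                 2 * pnorm(-abs(ss$beta / ss$standard_error)),
                 tolerance = 1e-10)
  }
  # configured heritability is matched by the true effects
  v <- 2 * g$exposure$effect_allele_frequency *
    (1 - g$exposure$effect_allele_frequency)
  expect_equal(sum(v * g$truth$gamma^2), 0.05, tolerance = 1e-12)
  # and recovered from the noisy betas within 10% relative error
  h2_hat <- sum(v * (g$exposure$beta^2 - g$exposure$standard_error^2))
  expect_lt(abs(h2_hat - 0.05) / 0.05, 0.10)
})

test_that("palindromic fraction controls strand-ambiguous allele coding", {
  g <- simulate_gwas_pair(gwas_sim_config(400, palindromic_fraction = 0.5, seed = 8))
  pal <- with(g$exposure, (effect_allele == "A" & other_allele == "T") |
                (effect_allele == "T" & other_allele == "A") |
                (effect_allele == "C" & other_allele == "G") |
                (effect_allele == "G" & other_allele == "C"))
  expect_gt(mean(pal), 0.40); expect_lt(mean(pal), 0.60)
})

test_that("twin cohort: estimates agree without confounding, attenuate under genetic confounding", {
  # no confounding: population, DZ-within and MZ-within all estimate theta
  cc <- cohort_config(2, 1, true_effects = 1.0, seed = 21)
  tw <- simulate_twin_cohort(cc, 2000, 2000, confounding = "none")
  pop <- fit_linear_assoc(tw$fi, tw$biomarker, cluster_ids = tw$pair_id)
  dz <- within_pair_estimate(tw, "DZ")
  mz <- within_pair_estimate(tw, "MZ")
  for (e in list(pop, dz, mz)) expect_lt(abs(e$beta - 1.0), 3 * e$se)
  # genetic confounding with zero direct effect: MZ-within ~ 0, population not
  cc0 <- cohort_config(2, 1, true_effects = 0, seed = 22)
  twg <- simulate_twin_cohort(cc0, 2000, 2000, confounding = "genetic",
                              confounder_effect = 2)
  popg <- fit_linear_assoc(twg$fi, twg$biomarker, cluster_ids = twg$pair_id)
  mzg <- within_pair_estimate(twg, "MZ")
  expect_lt(abs(mzg$beta), 2 * mzg$se)
  expect_gt(abs(popg$beta), 5 * popg$se)
})

test_that("an empty zygosity stratum is flagged", {
  cc <- cohort_config(2, 1, true_effects = 1, seed = 23)
  tw <- simulate_twin_cohort(cc, 0, 50, confounding = "none")
  expect_error(within_pair_estimate(tw, "MZ"), "fewer than 2 complete MZ pairs")
})
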