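test_that("within-pair estimator equals OLS on twin differences exactly", {
  cc <- cohort_config(2, 1, true_effects = 0.8, seed = 41)
  tw <- simulate_twin_cohort(cc, 60, 60, confounding = "none")
  wp <- within_pair_estimate(tw, "MZ", covariates = "bmi")
  # independent oracle: regression through the origin on pair differences
  mz <- tw[tw$zygosity == "MZ", ]
  d1 <- mz[mz$twin == 1, ]; d2 <- mz[mz$twin == 2, ]
  dy <- d1$fi - d2$fi
  X <- cbind(d1$biomarker - d2$biomarker, d1$bmi - d2$bmi)
  b <- solve(crossprod(X), crossprod(X, dy))
  expect_equal(wp$beta, b[1], tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("pair-shared exposure values leave the within-pair estimate undefined", {
  tw <- data.frame(pair_id = rep(1:5, each = 2), zygosity = "MZ",
                   twin = rep(1:2, 5), biomarker = rep(rnorm(5), each = 2),
                   fi = rnorm(10))
  expect_error(within_pair_estimate(tw, "MZ"), "exposure variance")
})

test_that("a fully pair-shared confounder moves the population but not the within-pair estimate", {
  cc <- cohort_config(2, 1, true_effects = 1.0, seed = 43)
  tw0 <- simulate_twin_cohort(cc, 1500, 1500, confounding = "none")
  tw1 <- simulate_twin_cohort(cc, 1500, 1500, confounding = "shared_env",
                              confounder_effect = 2)
  pop0 <- fit_linear_assoc(tw0$fi, tw0$biomarker, cluster_ids = tw0$pair_id)
  pop1 <- fit_linear_assoc(tw1$fi, tw1$biomarker, cluster_ids = tw1$pair_id)
  w0 <- within_pair_estimate(tw0)
  w1 <- within_pair_estimate(tw1)
  # population estimates differ by the confounder path
  expect_gt(abs(pop1$beta - pop0$beta), 3 * sqrt(pop0$se^2 + pop1$se^2))
  # within-pair estimates agree on the causal effect
  expect_lt(abs(w1$beta - 1.0), 3 * w1$se)
  expect_lt(abs(w0$beta - w1$beta), 3 * sqrt(w0$se^2 + w1$se^2))
})

test_that("co-twin interpretation labels follow the attenuation patterns", {
  est <- function(b, se) data.frame(beta = b, se = se)
  # no attenuation, tight intervals: causal-consistent
  r1 <- cotwin_compare(est(1, .05), est(1, .08), est(1, .08))
  expect_equal(r1$label, "causal-consistent")
  # pop > DZ > MZ with MZ interval covering zero: genetic confounding
  r2 <- cotwin_compare(est(1, .05), est(0.6, .1), est(0.1, .1))
  expect_equal(r2$label, "genetic-confounding-pattern")
  expect_equal(unname(r2$attenuation["dz_vs_pop"]), 0.6)
  # similar attenuation in both zygosities: shared environment
  r3 <- cotwin_compare(est(1, .05), est(0.35, .1), est(0.3, .1))
  expect_equal(r3$label, "shared-environment-pattern")
  # wide intervals everywhere: inconclusive
  r4 <- cotwin_compare(est(1, .05), est(0.9, 2), est(0.8, 2))
  expect_equal(r4$label, "inconclusive")
})

test_that("pipeline-grade twin run reproduces the genetic-confounding reading", {
  cc <- cohort_config(2, 1, true_effects = 0, seed = 44)
  tw <- simulate_twin_cohort(cc, 1200, 2700, confounding = "genetic",
                             confounder_effect = 2.5)
  pop <- fit_linear_assoc(tw$fi, tw$biomarker, cluster_ids = tw$pair_id)
  dz <- within_pair_estimate(tw, "DZ")
  mz <- within_pair_estimate(tw, "MZ")
  cmp <- cotwin_compare(pop, dz, mz)
  expect_equal(cmp$label, "genetic-confounding-pattern")
})
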