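test_that("standardization is the sample-SD z-score and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  x <- rnorm(100, 5, 3)
  z <- standardize(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
  zm <- standardize(cbind(a = x, b = 2 * x + 1))
  expect_equal(unname(colMeans(zm)), c(0, 0), tolerance = 1e-12)
})

test_that("outlier filter keeps values within k IQRs of the median", {
  x <- c(rep(8:12, 10), 21, 19)   # median 10, IQR 2 -> bounds [0, 20]
  keep <- filter_outliers(x, k = 5)
  expect_false(keep[length(x) - 1])   # 21 removed
  expect_true(keep[length(x)])        # 19 kept
  expect_warning(k2 <- filter_outliers(rep(3, 5)), "IQR is zero")
  expect_true(all(k2))
  # symmetric contamination on N(0,1) data is removed
  set.seed(7)
  y <- c(rnorm(1000), 100, -100)
  bounds <- median(y) + c(-5, 5) * IQR(y)
  expect_identical(filter_outliers(y), y >= bounds[1] & y <= bounds[2])
})

test_that("bonferroni thresholds", {
  expect_equal(bonferroni_threshold(200), 0.00025)
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(98), 0.05 / 98)
  expect_error(bonferroni_threshold(0), "at least 1")
})

test_that("association fit matches the closed-form WLS/OLS oracle", {
  set.seed(3)
  n <- 500
  z <- rnorm(n); age <- rnorm(n, 57, 8); sex <- rbinom(n, 1, .5)
  y <- 0.5 * z + 0.1 * age + rnorm(n)
  X <- cbind(1, z, age, sex)
  b <- solve(crossprod(X), crossprod(X, y))
  r <- fit_linear_assoc(y, z, data.frame(age = age, sex = sex))
  expect_equal(r$beta, b[2], tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(r$ci_low, r$beta - 1.96 * r$se)
  # classical SE oracle
  e <- y - X %*% b
  V <- drop(crossprod(e)) / (n - 4) * solve(crossprod(X))
  expect_equal(r$se, sqrt(V[2, 2]), tolerance = 1e-10)
})

test_that("cluster-robust SEs match the CR1 sandwich oracle; singleton clusters give HC1", {
  set.seed(4)
  n <- 120
  cl <- rep(1:40, each = 3)
  z <- rnorm(n); y <- 0.3 * z + rnorm(n)[cl] + rnorm(n, 0, .5)
  r <- fit_linear_assoc(y, z, cluster_ids = cl)
  X <- cbind(1, z)
  V <- cr1_oracle(X, y, cl)
  expect_equal(r$se, sqrt(V[2, 2]), tolerance = 1e-10)
  # all-singleton clusters: CR1 reduces to the HC1 heteroskedasticity sandwich
  r1 <- fit_linear_assoc(y, z, cluster_ids = seq_len(n))
  V1 <- cr1_oracle(X, y, seq_len(n))
  b <- solve(crossprod(X), crossprod(X, y))
  e <- drop(y - X %*% b)
  hc1 <- n / (n - 2) * solve(crossprod(X)) %*% crossprod(X * e) %*% solve(crossprod(X))
  expect_equal(sqrt(V1[2, 2]), sqrt(hc1[2, 2]), tolerance = 1e-10)
  expect_equal(r1$se, sqrt(hc1[2, 2]), tolerance = 1e-10)
})

test_that("degenerate designs error informatively", {
  y <- rnorm(50)
  expect_error(fit_linear_assoc(y, rep(1, 50)), "collinear|rank")
  x <- rnorm(50)
  expect_error(fit_linear_assoc(y, x, data.frame(a = x)), "collinear")
})

test_that("row permutation leaves estimates unchanged", {
  set.seed(5)
  n <- 200
  d <- data.frame(y = rnorm(n), z = rnorm(n), age = rnorm(n))
  r1 <- fit_linear_assoc(d$y, d$z, d["age"])
  p <- sample(n)
  r2 <- fit_linear_assoc(d$y[p], d$z[p], d[p, "age", drop = FALSE])
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$se, r2$se, tolerance = 1e-10)
})

test_that("run_screen flags against the family threshold and handles strata and FP", {
  cc <- cohort_config(4000, 6, true_effects = c(2.5, rep(0, 5)), seed = 31)
  co <- simulate_cohort(cc)
  d <- cbind(co$phenotypes, fi = compute_fi(co$deficits)$fi,
             fp = compute_fp(co$fp_criteria))
  bm <- paste0("bm", 1:6)
  sc <- run_screen(d, "fi", bm, c("age", "sex"), family_size = 200)
  expect_equal(attr(sc, "threshold"), 0.00025)
  expect_true(sc$flag[sc$id == "bm1"])
  # strata double the rows, threshold unchanged per stratum
  st <- run_screen(d, "fi", bm, c("sex"), family_size = 200,
                   strata = list(young = d$age < 60, old = d$age >= 60))
  expect_equal(nrow(st), 2 * length(bm))
  expect_equal(attr(st, "threshold"), 0.00025)
  # FP as outcome runs through identical machinery
  sf <- run_screen(d, "fp", bm, c("age", "sex"), family_size = 200)
  expect_equal(nrow(sf), length(bm))
  # empty stratum is skipped with a warning
  expect_warning(
    run_screen(d, "fi", bm[1], "sex", family_size = 200,
               strata = list(none = d$age > 1000, all = d$age < 1000)),
    "empty")
})

test_that("family-wise error is controlled under the global null", {
  set.seed(99)
  m <- 20; n <- 150
  thr <- bonferroni_threshold(m)
  any_flag <- vapply(1:500, function(r) {
    y <- rnorm(n)
    Z <- matrix(rnorm(n * m), n, m)
    p <- vapply(seq_len(m), function(j) {
      f <- fit_linear_assoc(y, Z[, j])
      f$p
    }, 0)
    any(p < thr)
  }, TRUE)
  expect_lte(mean(any_flag), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})
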