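---
title: "Methods: from deficit counts to causal estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from deficit counts to causal estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtymr)
```

## The problem

Frailty can be measured as deficit accumulation — the frailty index (FI),
the fraction of a fixed set of health deficits an individual carries,
reported here as a percentage — or as the frailty phenotype (FP), a count
of 0–5 Fried criteria. Many circulating biomarkers correlate with the FI,
but observational estimates mix causation, reverse causation and
confounding. This package chains the designs that triangulate on
causality: a large discovery screen, independent replication, two-sample
Mendelian randomization (MR) with pleiotropy-robust estimators, and
co-twin control. Because the cohort and GWAS data such analyses use are
access-restricted, the package ships a synthetic-data module that
reproduces the *statistical structure* each stage assumes, with the truth
recorded, so the whole pipeline is testable offline.

## Frailty measures

`compute_fi()` implements FI = 100 × (sum of deficits) / (non-missing
items). Two conventions matter and are fixed here:

* **Missingness**: individuals are excluded when *strictly more than* 20%
  of items are missing; an individual at exactly 20% is retained. With a
  49-item index, 10 missing items (20.4%) excludes, 9 (18.4%) does not.
* **Graded deficits**: item values may be any value in [0, 1], not only
  0/1, as deficit coding commonly grades severity.

`compute_fp()` refuses to score individuals with a missing criterion
(score set to `NA`) rather than scoring over fewer criteria; partial
scoring has no established definition and silently rescaling the count
would change its meaning. `strip_fi()` removes one of the 11 item
categories and recomputes the FI over the reduced denominator with the
same missingness rule — e.g. stripping the 8 cardiometabolic items of a
49-item index yields a 41-item FI. Stripping each category in turn gives
the 11 sensitivity outcomes used in the MR battery.

## The synthetic cohort generator

`simulate_cohort()` draws ages (default 56.77 ± 8.03 years), sex, a
block-correlated biomarker panel standardized within sample, and a binary
deficit matrix from a single latent liability $\eta$ with a logistic item
link: item $k$ is present with probability $\mathrm{logit}^{-1}(\alpha_k +
\eta_i)$. Design choices:

* **Item intercepts** $\alpha_k$ are log-spaced in prevalence (1%–45%),
  producing the right-skewed FI distribution seen in population cohorts,
  and are shifted by quadrature so the expected FI matches the target
  mean (default 12.29%).
* **Liability scale.** The liability is $\eta_i = u_i/K + \varepsilon_i$
  where $u_i$ collects the configured biomarker and covariate effects on
  the FI% scale. Because $(z, \eta)$ is jointly Gaussian, Stein's lemma
  gives the population OLS slope of FI on biomarker $z_j$ as
  $\beta_j \cdot E[m'(\eta)]/K$ with $m(\eta)$ the conditional mean FI;
  setting $K = E[m'(\eta)]$ (computed by Gauss–Hermite quadrature, no
  Monte Carlo) makes the generator's effects *exactly* the regression
  estimands, which the parameter-recovery tests rely on. The total
  liability spread is solved so the FI variance (between-individual plus
  item-level Bernoulli noise) matches the target SD (default 7.41).
* The FP criteria are 5 Bernoulli draws from the same liability with an
  intercept solved for the target mean score (default 0.56).

What the generator does *not* emulate: item-specific prevalences of any
real cohort (only the FI summary distribution is calibrated), age-varying
deficit trajectories, informative missingness, or non-Gaussian biomarker
tails. A green recovery test therefore establishes correctness of the
estimators under the stated linear-logistic world, not cohort realism.

`simulate_twin_cohort()` generates an additive-genetic factor correlated
1.0/0.5 within MZ/DZ pairs and a shared-environment factor correlated 1.0
within all pairs; under `confounding = "genetic"` (or `"shared_env"`) the
factor loads on both biomarker (weight 0.6) and FI, so population,
within-DZ and within-MZ regressions have the analytically ordered
estimands that the co-twin logic expects. The twin FI is generated
*linearly* on the percent scale (a Gaussian surrogate, not clipped to
[0, 100]): clipping would bias the within-pair oracle, and the co-twin
estimator only assumes linearity.

## The synthetic GWAS generator

`simulate_gwas_pair()` draws allele frequencies U(0.05, 0.95), scales true
per-SNP effects $\gamma_j$ so the instruments explain a configured
fraction of exposure variance, sets outcome effects $\beta_{Yj} =
\theta\gamma_j + \alpha_j$ (+ category-mediated components), uses the
standardized-trait GWAS approximation $se = 1/\sqrt{2p(1-p)n}$, and
computes exact Wald p-values, so $p = 2\Phi(-|\hat\beta/se|)$ holds to
machine precision. Pleiotropy regimes:

* *balanced*: $\alpha_j \sim N(0, \sigma_\alpha)$;
* *directional*: $\alpha_j \sim N(\mu_\alpha, \sigma_\alpha)$, applied in
  the **exposure-increasing allele orientation** (multiplied by
  $\mathrm{sign}(\gamma_j)$). This is deliberate: allele coding is
  arbitrary, so "directional" pleiotropy is only well defined relative to
  the allele that raises the exposure; without this orientation a sign
  flip of half the SNPs would symmetrize the effect and no estimator
  could detect a direction.
* *outlier*: a configured number of SNPs get a Wald ratio of (default)
  10× the causal effect.

When `category_mediation` routes a fraction of each SNP's outcome effect
through a deficit category, outcome summary statistics for each stripped
FI are emitted with that component removed — reproducing the structural
signature that stripped-FI MR is designed to detect.

## Estimator implementation notes

* **IVW** uses first-order weights $se_Y^{-2}$ and the multiplicative
  random-effects SE, floored at 1 (underdispersion never shrinks the SE).
* **MR-Egger** orients all SNPs to $\beta_X \ge 0$ before fitting (the
  estimator is not orientation invariant) and scales both SEs by
  $\max(1, \sqrt{Q_E/(J-2)})$. Weak instruments make the orientation
  unreliable; in the pipeline instruments always pass the $5\times
  10^{-8}$ threshold ($F \ge 29.7$), where sign error is negligible.
* **Weighted median** interpolates the inverse-variance-weighted
  percentiles at 0.5; **weighted mode** maximizes a weighted normal-kernel
  density (bandwidth $0.9\,\phi \min(s_w, IQR_w/1.34) J^{-1/5}$, 512-point
  grid). Both get SEs from a seeded parametric bootstrap (default 1000
  draws) resampling both betas from their sampling distributions.
* **MR-PRESSO** compares each SNP's weighted residual against its
  leave-one-out IVW expectation under a seeded simulation (default 1000).
  Empirical p-values use the add-one rule, so the smallest achievable
  Bonferroni-corrected per-SNP p is $J/(n_{sim}+1)$: with the default
  $n_{sim} = 1000$, outlier detection is possible for $J \le 50$ at
  $\alpha = 0.05$; raise `n_sim` for larger sets. The distortion test is
  not implemented; the raw-vs-corrected difference is reported
  descriptively instead.
* **Harmonization** resolves strand flips by complementing, drops
  palindromic SNPs with exposure-study MAF > 0.42, and aligns the
  remaining palindromic SNPs purely by allele frequency (letters carry no
  strand information for them). Harmonizing an already-aligned set is a
  no-op, and recoding both studies' alleles leaves all estimates
  unchanged.
* **Clumping** is greedy on ascending p with pairwise r² supplied either
  as a file or as synthetic block labels; a reference-panel reader is out
  of scope, since published analyses clump against unstated panels.
* **Single-instrument exposures** (common after pleiotropy pruning) fall
  back to the Wald ratio with delta-method SE, labeled `Wald_ratio`.
* **Screening** uses sample-SD standardization, complete-case models,
  normal-approximation 95% CIs (1.96; the cohorts are large), and CR1
  cluster-robust SEs for twin data — with all-singleton clusters CR1
  equals HC1 exactly, which the tests assert.
* **LASSO** delegates to `glmnet` with seeded fold assignment, penalty
  factor 0 for mandatory covariates (age/sex are adjustment terms, not
  candidates), MSE cross-validation, and the largest λ within one SE of
  the minimum (maximal sparsity under the 1-SE rule). The outcome is the
  raw FI in percent, matching the screen's effect scale.
* **Meta-analysis** uses the moment DL estimator; when $Q \le k-1$, τ² = 0
  and the result equals fixed-effect pooling exactly. "Replicated" means
  pooled p strictly below 0.05; directional consistency with discovery is
  available but off by default, as the replication criterion is the
  p-value alone.
* **BH-FDR** delegates to `stats::p.adjust`; the reported data-dependent
  threshold (largest rejected raw p) is the quantity analyses quote as
  "p < 0.011".

## Co-twin interpretation

`cotwin_compare()` encodes the qualitative reading as explicit CI-based
rules, in order: *inconclusive* when both within-pair intervals cover
both zero and the population estimate (no information either way);
*causal-consistent* when both within-pair intervals cover the population
point estimate; *genetic-confounding-pattern* when magnitudes order
population > DZ > MZ with the MZ interval covering zero;
*shared-environment-pattern* when DZ and MZ attenuate similarly (within a
configurable fraction, default 0.25, of the population magnitude). These
thresholds are deliberate package choices: the underlying reasoning in
the field is visual and qualitative.

## Determinism, sizes and budgets

Every stochastic routine requires an explicit seed (never defaulted) and
restores the RNG state, so identical configurations are byte-identical —
the pipeline writes a run log with every threshold, seed and family size
used. Stochastic test studies (IVW calibration at 500 replicates,
MR-PRESSO null study at 100 replicates × 500 simulations, LASSO selection
rates at 100 replicates) are sized to finish in a few minutes on one CPU;
they test calibration bands (e.g. type-I error in [0.03, 0.07]), not
point equalities.

## Known limitations

* LD is block-constant r²; no realistic MAF spectrum or LD decay.
* No multivariable MR, Steiger filtering, or distortion test.
* The twin generator produces same-sex pairs with pair-shared age only.
* FP is modelled as exchangeable Bernoulli criteria, ignoring the
  differing prevalences of the five Fried components.
* Non-linear biomarker–frailty dose–response is out of scope throughout;
  all models are linear in the standardized biomarker.
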