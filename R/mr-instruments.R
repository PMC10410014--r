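#' Validate a GWAS summary-statistics table
#'
#' Checks the GWAS-SSF-like column contract used throughout the MR engine:
#' variant_id, chromosome, base_pair_location (1-based), effect_allele,
#' other_allele, effect_allele_frequency in (0,1), beta, standard_error > 0,
#' p_value in (0,1], n.
#'
#' @param x data frame of per-SNP records.
#' @return \code{x}, invisibly, after validation.
#' @export
validate_summary_stats <- function(x) {
  missing_cols <- setdiff(summary_stats_columns, names(x))
  if (length(missing_cols))
    stopf("summary statistics missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  if (any(!x$effect_allele %in% c("A", "C", "G", "T")) ||
      any(!x$other_allele %in% c("A", "C", "G", "T")))
    stopf("alleles must be one of A, C, G, T")
  if (any(x$effect_allele == x$other_allele))
    stopf("effect and other allele must differ")
  if (any(x$standard_error <= 0)) stopf("standard errors must be positive")
  if (any(x$effect_allele_frequency <= 0 | x$effect_allele_frequency >= 1))
    stopf("effect allele frequencies must lie in (0,1)")
  invisible(x)
}

#' Select independent genome-wide-significant instruments
#'
#' Filters the exposure summary statistics at the significance threshold
#' (default p < 5e-8) and greedily clumps the survivors: repeatedly keep
#' the lowest-p SNP and discard all remaining SNPs within the window having
#' pairwise r2 at or above the threshold with it.
#'
#' @param exposure summary-statistics data frame.
#' @param p_threshold significance threshold, default 5e-8.
#' @param ld pairwise LD: data frame with columns snp_a, snp_b, r2 (pairs
#'   absent from the table are treated as r2 = 0); \code{NULL} means no LD.
#' @param r2_threshold clumping r2 threshold, default 0.001.
#' @param window_kb clumping window in kb, default 10000.
#' @return character vector of selected variant ids (empty, with a
#'   warning, if nothing passes the threshold).
#' @export
select_instruments <- function(exposure, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.001, window_kb = 10000) {
  validate_summary_stats(exposure)
  cand <- exposure[exposure$p_value < p_threshold, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warning("no SNP passes the significance threshold")
    return(character(0))
  }
  cand <- cand[order(cand$p_value), , drop = FALSE]
  r2_lookup <- build_r2_lookup(ld)
  kept <- character(0)
  window_bp <- window_kb * 1000
  while (nrow(cand) > 0L) {
    top <- cand[1L, ]
    kept <- c(kept, top$variant_id)
    cand <- cand[-1L, , drop = FALSE]
    if (nrow(cand) == 0L) break
    near <- cand$chromosome == top$chromosome &
      abs(cand$base_pair_location - top$base_pair_location) <= window_bp
    if (any(near)) {
      r2 <- vapply(cand$variant_id[near], function(s)
        r2_lookup(top$variant_id, s), 0)
      drop_ids <- cand$variant_id[near][r2 >= r2_threshold]
      cand <- cand[!cand$variant_id %in% drop_ids, , drop = FALSE]
    }
  }
  kept
}

build_r2_lookup <- function(ld) {
  if (is.null(ld) || nrow(ld) == 0L) return(function(a, b) 0)
  key <- c(paste(ld$snp_a, ld$snp_b), paste(ld$snp_b, ld$snp_a))
  val <- c(ld$r2, ld$r2)
  env <- new.env(hash = TRUE, size = length(key))
  for (i in seq_along(key)) assign(key[i], val[i], envir = env)
  function(a, b) {
    v <- mget(paste(a, b), envir = env, ifnotfound = 0)[[1L]]
    v
  }
}

complement_allele <- function(a) c(A = "T", T = "A", C = "G", G = "C")[a]

is_palindromic <- function(ea, oa) complement_allele(ea) == oa

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns per-SNP outcome records to the exposure's effect allele: swapped
#' allele codings get their beta sign flipped and EAF complemented; strand
#' flips are resolved by complementing alleles; strand-ambiguous (A/T, C/G)
#' SNPs with minor allele frequency above \code{palindromic_maf} (computed
#' in the exposure study) are dropped, and remaining palindromic SNPs are
#' aligned by allele frequency.  SNPs absent from the outcome are dropped.
#' Per-SNP Wald ratio estimates beta_Y/beta_X and first-order ratio SEs
#' se_Y/|beta_X| are attached.
#'
#' @param exposure,outcome summary-statistics data frames.
#' @param instruments character vector of variant ids (must be a subset of
#'   the exposure's SNPs), e.g. from [select_instruments()].
#' @param palindromic_maf MAF threshold above which palindromic SNPs are
#'   dropped, default 0.42.
#' @return data frame of class \code{harmonized_instruments} with columns
#'   variant_id, beta_exposure, se_exposure, eaf_exposure, beta_outcome,
#'   se_outcome, ratio, ratio_se, flipped; attribute \code{dropped}
#'   records the excluded SNPs and reasons.
#' @export
harmonize <- function(exposure, outcome, instruments,
                      palindromic_maf = 0.42) {
  validate_summary_stats(exposure)
  validate_summary_stats(outcome)
  if (!all(instruments %in% exposure$variant_id))
    stopf("instruments must be a subset of the exposure SNPs")
  ex <- exposure[match(instruments, exposure$variant_id), , drop = FALSE]
  keep <- logical(nrow(ex))
  flipped <- logical(nrow(ex))
  by <- se_y <- numeric(nrow(ex))
  dropped <- list()
  om <- match(ex$variant_id, outcome$variant_id)
  for (i in seq_len(nrow(ex))) {
    if (is.na(om[i])) {
      dropped[[length(dropped) + 1L]] <-
        data.frame(variant_id = ex$variant_id[i], reason = "dropped_missing")
      next
    }
    o <- outcome[om[i], ]
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    pal <- is_palindromic(ea, oa)
    if (pal) {
      maf <- min(ex$effect_allele_frequency[i], 1 - ex$effect_allele_frequency[i])
      if (maf > palindromic_maf) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(variant_id = ex$variant_id[i],
                     reason = "dropped_palindromic")
        next
      }
      # letters cannot resolve strand for palindromic SNPs: align by
      # allele frequency (effect alleles on the same side of 0.5 agree)
      same_letters <- (o$effect_allele == ea && o$other_allele == oa) ||
        (o$effect_allele == oa && o$other_allele == ea)
      if (!same_letters) {
        dropped[[length(dropped) + 1L]] <-
          data.frame(variant_id = ex$variant_id[i],
                     reason = "dropped_incompatible")
        next
      }
      # frequency is the only strand authority for palindromic SNPs:
      # outcome effect allele matches the exposure effect allele iff their
      # frequencies fall on the same side of 0.5
      freq_agree <- (ex$effect_allele_frequency[i] < 0.5) ==
        (o$effect_allele_frequency < 0.5)
      flip <- !freq_agree
      keep[i] <- TRUE
      flipped[i] <- flip
      by[i] <- if (flip) -o$beta else o$beta
      se_y[i] <- o$standard_error
      next
    }
    if (o$effect_allele == ea && o$other_allele == oa) {
      keep[i] <- TRUE; by[i] <- o$beta; se_y[i] <- o$standard_error
    } else if (o$effect_allele == oa && o$other_allele == ea) {
      keep[i] <- TRUE; flipped[i] <- TRUE
      by[i] <- -o$beta; se_y[i] <- o$standard_error
    } else {
      cea <- complement_allele(o$effect_allele)
      coa <- complement_allele(o$other_allele)
      if (cea == ea && coa == oa) {
        keep[i] <- TRUE; by[i] <- o$beta; se_y[i] <- o$standard_error
      } else if (cea == oa && coa == ea) {
        keep[i] <- TRUE; flipped[i] <- TRUE
        by[i] <- -o$beta; se_y[i] <- o$standard_error
      } else {
        dropped[[length(dropped) + 1L]] <-
          data.frame(variant_id = ex$variant_id[i],
                     reason = "dropped_incompatible")
      }
    }
  }
  out <- data.frame(
    variant_id = ex$variant_id[keep],
    beta_exposure = ex$beta[keep],
    se_exposure = ex$standard_error[keep],
    eaf_exposure = ex$effect_allele_frequency[keep],
    beta_outcome = by[keep],
    se_outcome = se_y[keep],
    stringsAsFactors = FALSE
  )
  out$ratio <- out$beta_outcome / out$beta_exposure
  out$ratio_se <- out$se_outcome / abs(out$beta_exposure)
  out$flipped <- flipped[keep]
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(variant_id = character(0), reason = character(0))
  class(out) <- c("harmonized_instruments", "data.frame")
  out
}

#' Per-SNP instrument strength F-statistics
#'
#' The first-stage strength of instrument j is F_j = (beta_Xj / se_Xj)^2;
#' the conventional weak-instrument rule of thumb requires F > 10.
#'
#' @param set a [harmonize()]d instrument set (or any data frame with
#'   beta_exposure and se_exposure columns).
#' @return list with per-SNP \code{f}, \code{mean_f} and \code{min_f}.
#' @export
f_statistic <- function(set) {
  f <- (set$beta_exposure / set$se_exposure)^2
  list(f = stats::setNames(f, set$variant_id), mean_f = mean(f), min_f = min(f))
}

#' Remove instruments associated with other exposures
#'
#' The pleiotropy-pruned sensitivity analysis re-runs MR on instruments
#' that are not genome-wide-significantly associated with any other
#' biomarker: any instrument reaching \code{p_threshold} in any of the
#' \code{other_exposures} is removed.
#'
#' @param instruments character vector of variant ids.
#' @param other_exposures named list of summary-statistics data frames.
#' @param p_threshold association threshold, default 5e-8.
#' @return list with \code{kept} (character vector) and \code{removed}
#'   (data frame variant_id/exposure); warns when nothing survives.
#' @export
prune_pleiotropic <- function(instruments, other_exposures,
                              p_threshold = 5e-8) {
  removed <- list()
  for (nm in names(other_exposures)) {
    oe <- other_exposures[[nm]]
    hit <- oe$variant_id[oe$p_value < p_threshold]
    bad <- intersect(instruments, hit)
    if (length(bad))
      removed[[length(removed) + 1L]] <-
        data.frame(variant_id = bad, exposure = nm, stringsAsFactors = FALSE)
  }
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(variant_id = character(0), exposure = character(0))
  kept <- setdiff(instruments, removed$variant_id)
  if (length(kept) == 0L && length(instruments) > 0L)
    warning("pleiotropy pruning left a highly reduced (empty) set of genetic instruments")
  list(kept = kept, removed = removed)
}
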