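#' Compute the deficit-accumulation frailty index
#'
#' The frailty index (FI) is the proportion of accumulated health deficits
#' across a fixed item set, expressed as a percentage.  For each individual
#' the FI is the sum of deficit values divided by the number of non-missing
#' items, multiplied by 100.  Individuals whose fraction of missing items
#' exceeds \code{max_missing_fraction} are excluded (FI set to \code{NA}).
#'
#' @param deficits numeric matrix or data frame, individuals x items; every
#'   non-missing entry must lie in \[0, 1\] (graded deficits allowed).
#' @param max_missing_fraction maximum tolerated fraction of missing items;
#'   individuals strictly above it are excluded.  Default 0.20.
#' @return data frame with columns \code{fi} (percent, \code{NA} when
#'   excluded), \code{n_items_used}, \code{excluded} and
#'   \code{exclude_reason}.
#' @examples
#' m <- matrix(0, 3, 49)
#' m[2, 1:10] <- 1                 # 10 deficits -> 100 * 10/49
#' m[3, 1:10] <- NA                # 10/49 > 20% missing -> excluded
#' compute_fi(m)
#' @export
compute_fi <- function(deficits, max_missing_fraction = 0.20) {
  deficits <- as.matrix(deficits)
  if (ncol(deficits) < 1L) stop("deficit matrix must have at least one item")
  bad <- which(!is.na(deficits) & (deficits < 0 | deficits > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    rid <- if (is.null(rownames(deficits))) i else rownames(deficits)[i]
    cid <- if (is.null(colnames(deficits))) j else colnames(deficits)[j]
    stop(sprintf("deficit value outside [0,1] for individual '%s', item '%s'",
                 rid, cid))
  }
  n_items <- ncol(deficits)
  n_miss <- rowSums(is.na(deficits))
  frac_miss <- n_miss / n_items
  excluded <- frac_miss > max_missing_fraction
  n_used <- n_items - n_miss
  fi <- 100 * rowSums(deficits, na.rm = TRUE) / pmax(n_used, 1L)
  fi[excluded | n_used == 0L] <- NA_real_
  data.frame(
    fi = fi,
    n_items_used = n_used,
    excluded = excluded,
    exclude_reason = ifelse(excluded,
                            sprintf("missing fraction %.3f > %.2f",
                                    frac_miss, max_missing_fraction), ""),
    stringsAsFactors = FALSE
  )
}

#' Compute the frailty phenotype score
#'
#' Counts how many of the five Fried frailty criteria (weight loss,
#' exhaustion, slowness, low physical activity, weakness) are present.
#' The score is an integer 0-5, treated as continuous downstream.  Any
#' individual with a missing criterion gets an \code{NA} score.
#'
#' @param criteria logical (or 0/1) matrix/data frame, individuals x 5.
#' @return integer vector of FP scores, \code{NA} where any criterion is
#'   missing.
#' @export
compute_fp <- function(criteria) {
  criteria <- as.matrix(criteria)
  if (ncol(criteria) != 5L)
    stop("frailty phenotype requires exactly 5 criteria, got ", ncol(criteria))
  mode(criteria) <- "integer"
  if (any(!is.na(criteria) & !(criteria %in% c(0L, 1L))))
    stop("criteria must be logical or 0/1")
  fp <- rowSums(criteria)
  as.integer(fp)
}

#' Frailty index stripped of one deficit category
#'
#' Recomputes the FI after removing all items belonging to one category
#' (e.g. the 8 cardiometabolic items of a 49-item index, leaving a 41-item
#' FI).  The same missingness rule is applied against the reduced
#' denominator.  Stripping each of the categories in turn yields the
#' battery of modified FIs used as sensitivity outcomes.
#'
#' @param deficits individuals x items matrix as for [compute_fi()].
#' @param category_map character vector, one category label per item
#'   (length \code{ncol(deficits)}).
#' @param category label of the category to strip.
#' @inheritParams compute_fi
#' @return as [compute_fi()], computed on the reduced item set.
#' @export
strip_fi <- function(deficits, category_map, category,
                     max_missing_fraction = 0.20) {
  deficits <- as.matrix(deficits)
  if (length(category_map) != ncol(deficits))
    stop("category_map must have one label per item")
  if (!category %in% category_map)
    stop("unknown category '", category, "'; valid categories: ",
         paste(sort(unique(category_map)), collapse = ", "))
  keep <- category_map != category
  compute_fi(deficits[, keep, drop = FALSE], max_missing_fraction)
}
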