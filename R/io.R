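# Tab/comma-separated readers and writers for the pipeline's interchange
# formats.  All tables are plain text with fixed, documented headers so
# outputs diff cleanly; writers and readers round-trip exactly.

write_tsv_impl <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read / write GWAS summary statistics (TSV)
#'
#' Tab-separated with the GWAS-SSF-aligned header: variant_id, chromosome,
#' base_pair_location, effect_allele, other_allele,
#' effect_allele_frequency, beta, standard_error, p_value, n.  Positions
#' are 1-based integers.  Malformed files are rejected with the offending
#' column or line named.
#'
#' @param path file path.
#' @return data frame of validated summary statistics.
#' @export
read_summary_stats <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(summary_stats_columns, names(x))
  if (length(missing_cols))
    stopf("parse error in '%s': missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  pos_num <- suppressWarnings(as.numeric(x$base_pair_location))
  bad <- which(is.na(pos_num) | pos_num != floor(pos_num))
  if (length(bad))
    stopf("parse error in '%s': non-integer base_pair_location at line %d",
          path, bad[1L] + 1L)  # +1 for the header line
  for (col in c("effect_allele_frequency", "beta", "standard_error",
                "p_value", "n")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v))
      stopf("parse error in '%s': non-numeric %s at line %d", path, col,
            which(is.na(v))[1L] + 1L)
    x[[col]] <- v
  }
  x$base_pair_location <- as.integer(pos_num)
  x$chromosome <- suppressWarnings(as.integer(x$chromosome))
  x$n <- as.numeric(x$n)
  x <- x[summary_stats_columns]
  validate_summary_stats(x)
  x
}

#' @rdname read_summary_stats
#' @param x summary-statistics data frame.
#' @export
write_summary_stats <- function(x, path) {
  validate_summary_stats(x)
  write_tsv_impl(x[summary_stats_columns], path)
  invisible(path)
}

#' Read / write pairwise LD tables (TSV: snp_a, snp_b, r2)
#' @param path file path.
#' @return data frame with columns snp_a, snp_b, r2.
#' @export
read_ld <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("snp_a", "snp_b", "r2")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stopf("parse error in '%s': missing column(s) %s", path,
          paste(missing_cols, collapse = ", "))
  x[need]
}

#' @rdname read_ld
#' @param x LD data frame.
#' @export
write_ld <- function(x, path) {
  write_tsv_impl(x[c("snp_a", "snp_b", "r2")], path)
  invisible(path)
}

#' Read / write phenotype tables (CSV)
#'
#' One row per individual; columns are free-form (ids, covariates,
#' biomarkers, deficit items).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_phenotypes
#' @param x phenotype data frame.
#' @export
write_phenotypes <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Write a results table (TSV)
#' @param x results data frame (screen, meta, MR battery, co-twin).
#' @param path file path.
#' @export
write_results <- function(x, path) {
  write_tsv_impl(as.data.frame(x), path)
  invisible(path)
}
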