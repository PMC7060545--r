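#' Select genome-wide significant instruments
#'
#' Keeps the rows with `pval` strictly below `p_threshold` (the conventional
#' genome-wide significance filter), preserving input order.
#'
#' @param assocs Canonical summary-statistics data.frame.
#' @param p_threshold Strict p-value cutoff in (0, 1); default `5e-8`.
#' @return The filtered data.frame.
#' @export
select_genomewide <- function(assocs, p_threshold = 5e-8) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold < 1)
  assocs[assocs$pval < p_threshold, , drop = FALSE]
}

#' Exclude instruments associated with secondary phenotypes
#'
#' Removes harmonized instruments whose rsid — or, for proxy rows, the
#' original instrument rsid in `proxy_of` — appears in the exclusion list.
#' Used for sensitivity analyses dropping variants associated with traits
#' other than the exposure.
#'
#' @param instruments Harmonized-instrument data.frame
#'   (see [harmonize_instruments()]).
#' @param exclusion_list Character vector of rsids, or a data.frame with an
#'   `rsid` column (a `trait` column, if present, is informational only).
#' @return The retained instruments.
#' @export
exclude_secondary_phenotypes <- function(instruments, exclusion_list) {
  if (is.data.frame(exclusion_list)) exclusion_list <- exclusion_list$rsid
  exclusion_list <- unique(as.character(exclusion_list))
  hit <- instruments$rsid %in% exclusion_list |
    (!is.na(instruments$proxy_of) & instruments$proxy_of %in% exclusion_list)
  unmatched <- setdiff(exclusion_list, c(instruments$rsid, stats::na.omit(instruments$proxy_of)))
  if (length(unmatched))
    message(sprintf("exclusion list: %d rsid(s) not among the instruments (ignored)", length(unmatched)))
  message(sprintf("secondary-phenotype exclusion removed %d of %d instruments", sum(hit), nrow(instruments)))
  instruments[!hit, , drop = FALSE]
}

#' Instrument-strength F-statistic
#'
#' Set-level approximation `F = R2 (n - k - 1) / (k (1 - R2))` from the
#' variance in the exposure explained jointly by the `k` instruments in a
#' GWAS of `n` individuals. Values well above 10 indicate little
#' weak-instrument bias.
#'
#' @param r2_explained Fraction of exposure variance explained, in (0, 1).
#' @param n_exposure Exposure GWAS sample size.
#' @param k Number of instruments; must satisfy `n_exposure > k + 1`.
#' @return The F value.
#' @export
f_statistic <- function(r2_explained, n_exposure, k) {
  if (!is.numeric(r2_explained) || r2_explained <= 0 || r2_explained >= 1)
    stopf("r2_explained must lie in (0,1)")
  if (k < 1) stopf("k must be >= 1")
  if (n_exposure <= k + 1) stopf("n_exposure must exceed k + 1")
  r2_explained * (n_exposure - k - 1) / (k * (1 - r2_explained))
}
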