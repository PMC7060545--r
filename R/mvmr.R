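#' Multivariable inverse-variance weighted MR
#'
#' Joint estimation of the direct effect of each exposure on the outcome:
#' weighted least squares of the per-SNP outcome betas on the matrix of
#' exposure betas, no intercept, weights `se_outcome^-2`. Standard errors
#' are inflated by `max(1, sqrt(RSS_w / (k - m)))` (multiplicative random
#' effects) and inference uses normal quantiles. With a single exposure
#' this reduces exactly to the univariable random-effects IVW.
#'
#' @param mvdat Data.frame with columns `beta_outcome`, `se_outcome` and a
#'   `beta_<name>` / `se_<name>` pair per exposure (an `rsid` column is
#'   carried if present).
#' @param exposure_names Exposure labels; inferred from the `beta_*`
#'   columns when `NULL`.
#' @return Named list of `mr_estimate` objects, one per exposure, with an
#'   attribute `"rss_w"` (weighted residual sum of squares).
#' @export
mr_mvivw <- function(mvdat, exposure_names = NULL) {
  if (is.null(exposure_names)) {
    bcols <- grep("^beta_", names(mvdat), value = TRUE)
    exposure_names <- sub("^beta_", "", setdiff(bcols, "beta_outcome"))
  }
  m <- length(exposure_names)
  if (m < 1) stopf("no exposures found")
  need <- c(paste0("beta_", exposure_names), "beta_outcome", "se_outcome")
  miss <- setdiff(need, names(mvdat))
  if (length(miss)) stopf("mvdat missing column(s): %s", paste(miss, collapse = ", "))
  k <- nrow(mvdat)
  if (k <= m) stopf("multivariable IVW requires k > m (k = %d, m = %d)", k, m)
  X <- as.matrix(mvdat[, paste0("beta_", exposure_names), drop = FALSE])
  y <- mvdat$beta_outcome
  w <- mvdat$se_outcome^-2
  qrX <- qr(sqrt(w) * X)
  if (qrX$rank < m) {
    dep <- exposure_names[setdiff(seq_len(m), qrX$pivot[seq_len(qrX$rank)])]
    stopf("rank-deficient exposure design: collinear column(s) %s", paste(dep, collapse = ", "))
  }
  fit <- stats::lm(y ~ 0 + X, weights = w)
  sigma <- summary(fit)$sigma          # sqrt(RSS_w / (k - m))
  se_unscaled <- sqrt(diag(stats::vcov(fit))) / sigma
  scale <- max(1, sigma)
  coefs <- stats::coef(fit)
  rss_w <- sum(w * stats::resid(fit)^2)
  out <- lapply(seq_len(m), function(j) {
    est <- new_mr_estimate(paste0("mvivw_", exposure_names[j]),
                           unname(coefs[j]), unname(se_unscaled[j]) * scale, k)
    est$q_stat <- rss_w
    est$q_pval <- stats::pchisq(rss_w, df = k - m, lower.tail = FALSE)
    est
  })
  names(out) <- exposure_names
  attr(out, "rss_w") <- rss_w
  out
}

#' Read a multivariable MR input table
#'
#' @param path Headered TSV/CSV with `rsid`, one `beta_<name>` /
#'   `se_<name>` pair per exposure, `beta_outcome` and `se_outcome`.
#' @return Validated data.frame (all SE columns positive).
#' @export
read_mvmr_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                         stringsAsFactors = FALSE, check.names = FALSE)
  secols <- grep("^se_", names(d), value = TRUE)
  if (!all(c("beta_outcome", "se_outcome") %in% names(d)))
    stopf("MVMR table must contain beta_outcome and se_outcome")
  for (s in secols) if (any(!is.finite(d[[s]]) | d[[s]] <= 0))
    stopf("MVMR table: non-positive or missing values in %s", s)
  d
}
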