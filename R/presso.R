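# Leave-one-out IVW slopes for a weighted regression-through-origin of y on
# x with weights w: slope_(-j) = (Sxy - w_j x_j y_j) / (Sxx - w_j x_j^2).
loo_slopes <- function(x, y, w) {
  sxy <- sum(w * x * y); sxx <- sum(w * x^2)
  (sxy - w * x * y) / (sxx - w * x^2)
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Simulation-based test for horizontal pleiotropy. For each instrument the
#' leave-one-out IVW slope predicts its outcome beta; the observed residual
#' sum of squares (RSS) is compared against RSS values from datasets
#' simulated under the no-pleiotropy model (betas redrawn from their
#' reported sampling distributions around the leave-one-out fit, residuals
#' recomputed by the identical leave-one-out procedure). The global p-value
#' is the add-one empirical tail probability; per-SNP outlier p-values
#' compare each squared standardized residual with its own simulated
#' distribution and are Bonferroni-corrected. Flagged outliers are removed
#' and the random-effects IVW re-estimated.
#'
#' @param instruments Harmonized-instrument data.frame; at least 4 rows.
#' @param n_sim Number of simulated datasets; default
#'   `max(10000, ceiling(k / alpha))` so that Bonferroni-corrected p-values
#'   retain resolution below `alpha / k`.
#' @param alpha Outlier significance level on the Bonferroni scale
#'   (default 0.05).
#' @param seed Mandatory RNG seed.
#' @return List of class `mr_presso`: `rss_obs`, `p_global`, `per_snp`
#'   (rsid, rss_contribution, p_outlier_raw, p_outlier_bonferroni, flagged),
#'   `outliers`, `corrected` (`mr_estimate`, random-effects IVW on the
#'   non-outliers), `n_sim`, `alpha`, `seed`.
#' @export
mr_presso <- function(instruments, n_sim = NULL, alpha = 0.05, seed) {
  k <- nrow(instruments)
  if (k < 4) stopf("MR-PRESSO requires k >= 4 instruments, got %d", k)
  if (missing(seed)) stopf("mr_presso: an explicit seed is required")
  n_sim <- n_sim %||% max(10000L, as.integer(ceiling(k / alpha)))
  n_sim <- as.integer(n_sim)
  if (n_sim < 1000) warnf("n_sim = %d gives coarse p-value resolution (1/%d)", n_sim, n_sim + 1L)

  x <- instruments$beta_exposure; y <- instruments$beta_outcome
  sx <- instruments$se_exposure;  sy <- instruments$se_outcome
  w <- sy^-2
  loo <- loo_slopes(x, y, w)
  r_obs <- (y - loo * x) / sy
  rss_obs <- sum(r_obs^2)
  r2_obs <- r_obs^2

  # accumulate exceedance counts over simulation blocks (bounded memory)
  set.seed(seed)
  exceed_global <- 0L
  exceed_snp <- integer(k)
  block <- 2500L
  done <- 0L
  while (done < n_sim) {
    b <- min(block, n_sim - done)
    xs <- matrix(stats::rnorm(k * b, mean = x, sd = sx), nrow = k)
    ys <- matrix(stats::rnorm(k * b, mean = loo * x, sd = sy), nrow = k)
    wxy <- w * xs * ys; wxx <- w * xs^2
    sxy_s <- colSums(wxy); sxx_s <- colSums(wxx)
    loo_s <- (rep(sxy_s, each = k) - wxy) / (rep(sxx_s, each = k) - wxx)
    r2_s <- ((ys - loo_s * xs) / sy)^2
    exceed_global <- exceed_global + sum(colSums(r2_s) >= rss_obs)
    exceed_snp <- exceed_snp + rowSums(r2_s >= r2_obs)
    done <- done + b
  }
  p_global <- (exceed_global + 1) / (n_sim + 1)
  p_raw <- (exceed_snp + 1) / (n_sim + 1)
  p_bonf <- pmin(1, k * p_raw)
  flagged <- p_bonf < alpha

  res <- structure(list(
    rss_obs = rss_obs, p_global = p_global,
    per_snp = data.frame(rsid = instruments$rsid, rss_contribution = r2_obs,
                         p_outlier_raw = p_raw, p_outlier_bonferroni = p_bonf,
                         flagged = flagged, stringsAsFactors = FALSE),
    outliers = instruments$rsid[flagged],
    corrected = NULL, n_sim = n_sim, alpha = alpha, seed = seed,
    instruments = instruments), class = "mr_presso")
  res$corrected <- presso_corrected(instruments, res$outliers)
  res
}

#' Re-threshold MR-PRESSO outliers at a different significance level
#'
#' Reuses the per-SNP simulated-residual p-values stored in an `mr_presso`
#' result; no re-simulation.
#'
#' @param presso An `mr_presso` result.
#' @param alpha New Bonferroni-scale significance level.
#' @return The updated `mr_presso` result.
#' @export
presso_outliers <- function(presso, alpha = 0.05) {
  stopifnot(inherits(presso, "mr_presso"))
  presso$alpha <- alpha
  presso$per_snp$flagged <- presso$per_snp$p_outlier_bonferroni < alpha
  presso$outliers <- presso$per_snp$rsid[presso$per_snp$flagged]
  presso$corrected <- presso_corrected(presso$instruments, presso$outliers)
  presso
}

#' Outlier-corrected IVW estimate
#'
#' Random-effects IVW on the instrument set with the flagged outliers
#' removed. With an empty outlier set this is the plain IVW.
#'
#' @param instruments Harmonized-instrument data.frame.
#' @param outliers Character vector of rsids to remove.
#' @return An `mr_estimate`.
#' @export
presso_corrected <- function(instruments, outliers) {
  keep <- instruments[!instruments$rsid %in% outliers, , drop = FALSE]
  if (nrow(keep) < 2) stopf("too few instruments remain after outlier removal (%d)", nrow(keep))
  est <- mr_ivw(keep, model = "random")
  est$method <- "presso_corrected"
  est
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.2f, global p = %.4g (%d simulations)\n",
              x$rss_obs, x$p_global, x$n_sim))
  cat(sprintf("  outliers flagged at alpha = %g: %d%s\n", x$alpha, length(x$outliers),
              if (length(x$outliers)) paste0(" (", paste(x$outliers, collapse = ", "), ")") else ""))
  if (!is.null(x$corrected)) { cat("  corrected: "); print(x$corrected) }
  invisible(x)
}
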