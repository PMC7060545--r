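#' Per-SNP Wald ratio estimates
#'
#' The ratio estimate for each instrument: SNP-outcome beta over
#' SNP-exposure beta, with a first-order (default) or second-order
#' delta-method standard error. First-order ignores the uncertainty of the
#' exposure beta, matching the weighting convention of the summary-data MR
#' estimators implemented here.
#'
#' @param instruments Harmonized-instrument data.frame.
#' @param se_order `"first"`: `se = se_Y / |beta_X|`; `"second"` adds the
#'   exposure-beta uncertainty,
#'   `se = sqrt(se_Y^2/beta_X^2 + beta_Y^2 se_X^2 / beta_X^4)`.
#' @return Data.frame with `rsid`, `theta` (ratio), `se`, `weight`
#'   (inverse-variance).
#' @export
wald_ratios <- function(instruments, se_order = c("first", "second")) {
  se_order <- match.arg(se_order)
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  sx <- instruments$se_exposure;   sy <- instruments$se_outcome
  if (any(bx == 0)) stopf("null instrument: beta_exposure = 0 for %s",
                          paste(instruments$rsid[bx == 0], collapse = ", "))
  theta <- by / bx
  se <- if (se_order == "first") sy / abs(bx) else sqrt(sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  data.frame(rsid = instruments$rsid, theta = theta, se = se, weight = se^-2,
             stringsAsFactors = FALSE)
}

new_mr_estimate <- function(method, beta, se, k, q_stat = NA_real_, q_pval = NA_real_) {
  z <- stats::qnorm(0.975)
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - z * se, ci_high = beta + z * se,
    pval = two_sided_p(beta, se),
    or = exp(beta), or_low = exp(beta - z * se), or_high = exp(beta + z * se),
    k = k, q_stat = q_stat, q_pval = q_pval), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (k = %d): OR %.3f (95%% CI %.3f-%.3f), beta %.4f (SE %.4f), p = %.3g\n",
              x$method, x$k, x$or, x$or_low, x$or_high, x$beta, x$se, x$pval))
  if (is.finite(x$q_stat))
    cat(sprintf("  Cochran's Q = %.2f on %d df, p = %.3g\n", x$q_stat, x$k - 1L, x$q_pval))
  invisible(x)
}

#' Inverse-variance weighted estimate
#'
#' Pools the per-SNP Wald ratios by inverse-variance weighting; identical to
#' a weighted zero-intercept regression of outcome betas on exposure betas
#' with weights `se_outcome^-2` (for first-order weights). The
#' multiplicative random-effects model inflates the fixed-effect standard
#' error by `sqrt(Q / (k - 1))` whenever Cochran's Q exceeds its
#' expectation, never deflating it.
#'
#' @param instruments Harmonized-instrument data.frame.
#' @param model `"random"` (default) or `"fixed"`.
#' @param se_order Wald-ratio SE order, see [wald_ratios()].
#' @return An `mr_estimate`: log-odds `beta`, `se`, normal 95% CI and
#'   two-sided p, the exponentiated (odds-ratio) scale, `k`, and Cochran's
#'   Q with its p-value.
#' @export
mr_ivw <- function(instruments, model = c("random", "fixed"), se_order = "first") {
  model <- match.arg(model)
  k <- nrow(instruments)
  if (k < 1 || (model == "random" && k < 2))
    stopf("ivw requires k >= %d instruments, got %d", if (model == "random") 2L else 1L, k)
  r <- wald_ratios(instruments, se_order)
  w <- r$weight
  beta <- sum(w * r$theta) / sum(w)
  se_fixed <- sum(w)^-0.5
  q <- sum(w * (r$theta - beta)^2)
  q_pval <- if (k >= 2) stats::pchisq(q, df = k - 1, lower.tail = FALSE) else NA_real_
  se <- if (model == "random") se_fixed * max(1, sqrt(q / (k - 1))) else se_fixed
  new_mr_estimate(paste0("ivw_", model), beta, se, k, q, q_pval)
}

# Weighted median of ratio estimates: sort ratios, interpolate the
# weight-standardized cumulative distribution at 1/2.
weighted_median_point <- function(theta, weight) {
  ord <- order(theta)
  th <- theta[ord]; w <- weight[ord]
  s <- (cumsum(w) - w / 2) / sum(w)
  hit <- which(s == 0.5)
  if (length(hit)) return(th[hit[1]])
  if (0.5 <= s[1]) return(th[1])
  if (0.5 >= s[length(s)]) return(th[length(th)])
  j <- max(which(s < 0.5))
  th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median estimate
#'
#' Median of the inverse-variance-weighted ratio distribution; consistent
#' when instruments carrying at least half the weight are valid. The point
#' estimate is deterministic; the standard error comes from a parametric
#' bootstrap resampling both betas from their reported sampling
#' distributions.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 10000).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @return An `mr_estimate` (Q fields refer to the IVW ratio dispersion).
#' @export
mr_weighted_median <- function(instruments, n_boot = 10000, seed, se_order = "first") {
  k <- nrow(instruments)
  if (k < 3) stopf("weighted median requires k >= 3 instruments, got %d", k)
  if (missing(seed)) stopf("mr_weighted_median: an explicit seed is required")
  r <- wald_ratios(instruments, se_order)
  point <- weighted_median_point(r$theta, r$weight)
  bx <- instruments$beta_exposure; by <- instruments$beta_outcome
  sx <- instruments$se_exposure;   sy <- instruments$se_outcome
  boot <- numeric(n_boot)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    bxs <- stats::rnorm(k, bx, sx)
    bys <- stats::rnorm(k, by, sy)
    ths <- bys / bxs
    ws <- (sy / abs(bxs))^-2
    boot[b] <- weighted_median_point(ths, ws)
  }
  se <- stats::sd(boot)
  est <- new_mr_estimate("weighted_median", point, se, k)
  q <- cochran_q(instruments, sum(r$weight * r$theta) / sum(r$weight), se_order)
  est$q_stat <- q$q; est$q_pval <- q$pval
  est
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with an
#' unconstrained intercept, after orienting every instrument to a positive
#' exposure beta. A non-zero intercept estimates the average directional
#' pleiotropic effect; the slope is a pleiotropy-adjusted causal estimate
#' under the InSIDE assumption. Coefficient standard errors are inflated by
#' `max(1, sqrt(RSS_w / (k - 2)))` (multiplicative random effects) and
#' inference uses normal quantiles.
#'
#' @inheritParams mr_ivw
#' @return List of class `mr_egger`: `slope` (`mr_estimate`), `intercept`,
#'   `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(instruments) {
  k <- nrow(instruments)
  if (k < 3) stopf("MR-Egger requires k >= 3 instruments, got %d", k)
  sgn <- ifelse(instruments$beta_exposure < 0, -1, 1)
  x <- instruments$beta_exposure * sgn
  y <- instruments$beta_outcome * sgn
  w <- instruments$se_outcome^-2
  if (stats::sd(x) < sqrt(.Machine$double.eps) * max(1, mean(abs(x))))
    stopf("degenerate regressor: no spread in oriented exposure betas")
  fit <- stats::lm(y ~ x, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma                      # sqrt(RSS_w / (k - 2))
  se_unscaled <- sqrt(diag(stats::vcov(fit))) / sigma
  scale <- max(1, sigma)
  coefs <- stats::coef(fit)
  rss_w <- sum(w * stats::resid(fit)^2)
  slope <- new_mr_estimate("egger_slope", unname(coefs["x"]),
                           unname(se_unscaled["x"]) * scale, k,
                           q_stat = rss_w,
                           q_pval = stats::pchisq(rss_w, df = k - 2, lower.tail = FALSE))
  int_se <- unname(se_unscaled["(Intercept)"]) * scale
  structure(list(slope = slope,
                 intercept = unname(coefs["(Intercept)"]),
                 intercept_se = int_se,
                 intercept_pval = two_sided_p(unname(coefs["(Intercept)"]), int_se)),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  print(x$slope)
  cat(sprintf("  intercept %.4f (SE %.4f), p = %.3g\n",
              x$intercept, x$intercept_se, x$intercept_pval))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' @inheritParams mr_ivw
#' @param beta Pooled estimate around which heterogeneity is measured.
#' @return List with `q`, `df` (`k - 1`) and the chi-square upper-tail `pval`.
#' @export
cochran_q <- function(instruments, beta, se_order = "first") {
  k <- nrow(instruments)
  if (k < 2) stopf("Cochran's Q requires k >= 2 instruments")
  r <- wald_ratios(instruments, se_order)
  q <- sum(r$weight * (r$theta - beta)^2)
  list(q = q, df = k - 1L, pval = stats::pchisq(q, df = k - 1, lower.tail = FALSE))
}

#' Format an estimate as a forest-table row
#'
#' @param est An `mr_estimate`.
#' @return One-row data.frame with the method, instrument count, odds ratio
#'   and CI bounds formatted to two decimals, a compact
#'   `"OR x.xx (lo-hi)"` label, and the p-value in scientific notation.
#' @export
to_forest_row <- function(est) {
  data.frame(
    method = est$method, n_snp = est$k,
    or = sprintf("%.2f", est$or),
    or_lo95 = sprintf("%.2f", est$or_low),
    or_hi95 = sprintf("%.2f", est$or_high),
    label = sprintf("OR %.2f (%.2f–%.2f)", est$or, est$or_low, est$or_high),
    pval = sprintf("%.2e", est$pval),
    stringsAsFactors = FALSE)
}
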