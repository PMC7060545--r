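#' Configuration for the synthetic two-sample GWAS generator
#'
#' Defaults emulate the smoking-initiation to rheumatoid-arthritis
#' configuration: 367 conditionally independent instruments jointly
#' explaining 2.3% of exposure variance in a 1,232,091-individual exposure
#' GWAS, a binary outcome GWAS of 14,361 cases and 43,923 controls, and a
#' true causal log-odds effect of `log(1.32)`.
#'
#' @param k Instrument count.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case-control sample sizes.
#' @param theta True causal effect on the log-odds scale.
#' @param r2_target Exposure variance jointly explained by the instruments.
#' @param pleiotropy_mode `"none"`, `"balanced"` (pleiotropic effects
#'   centred on zero), `"directional"` (non-zero mean `mu_alpha`), or
#'   `"inside_violating"` (pleiotropic effect correlated with instrument
#'   strength: `mu_alpha + q_inside * gamma + noise`).
#' @param pi_pleio Fraction of instruments with a pleiotropic effect; the
#'   count is fixed at `round(pi_pleio * k)`.
#' @param mu_alpha,sigma_alpha Mean and SD of the pleiotropic effects.
#' @param q_inside Strength-coupling coefficient for `"inside_violating"`.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param missing_frac Fraction of instruments absent from the outcome table.
#' @param proxy_frac Fraction of the missing instruments recoverable via an
#'   LD proxy.
#' @param r2_proxy_range Uniform range for proxy LD r-squared.
#' @param seed Mandatory RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k = 367, n_exposure = 1232091,
                       n_cases = 14361, n_controls = 43923,
                       theta = log(1.32), r2_target = 0.023,
                       pleiotropy_mode = c("none", "balanced", "directional", "inside_violating"),
                       pi_pleio = 0, mu_alpha = 0, sigma_alpha = 0, q_inside = 0,
                       maf_range = c(0.05, 0.5),
                       missing_frac = 0, proxy_frac = 0,
                       r2_proxy_range = c(0.9, 1.0), seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stopf("sim_config: an explicit seed is required")
  cfg <- list(k = as.integer(k), n_exposure = n_exposure, n_cases = n_cases,
              n_controls = n_controls, theta = theta, r2_target = r2_target,
              pleiotropy_mode = pleiotropy_mode, pi_pleio = pi_pleio,
              mu_alpha = mu_alpha, sigma_alpha = sigma_alpha, q_inside = q_inside,
              maf_range = maf_range, missing_frac = missing_frac,
              proxy_frac = proxy_frac, r2_proxy_range = r2_proxy_range,
              seed = as.integer(seed))
  if (cfg$k < 4) stopf("k must be >= 4")
  if (cfg$r2_target <= 0 || cfg$r2_target >= 1) stopf("r2_target must lie in (0,1)")
  for (f in c("pi_pleio", "missing_frac", "proxy_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stopf("%s must lie in [0,1]", f)
  if (any(cfg$maf_range <= 0) || any(cfg$maf_range > 0.5) || diff(cfg$maf_range) < 0)
    stopf("maf_range must be an increasing range within (0, 0.5]")
  if (any(cfg$r2_proxy_range < 0) || any(cfg$r2_proxy_range > 1) || diff(cfg$r2_proxy_range) < 0)
    stopf("r2_proxy_range must be an increasing range within [0,1]")
  structure(cfg, class = "sim_config")
}

# non-palindromic allele pairs only, so the default harmonization policy
# never drops simulated instruments
sim_allele_pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"),
                          c("A", "C"), c("C", "A"), c("G", "T"), c("T", "G"))

#' Simulate a two-sample GWAS summary-statistics dataset
#'
#' Generates exposure and outcome summary-statistics tables with known
#' latent truth. Per-SNP true exposure effects are drawn and rescaled so the
#' instruments jointly explain exactly `r2_target` of exposure variance;
#' standard errors follow the standard `1/sqrt(2 f (1-f) n)` form, with the
#' binary outcome using the effective sample size
#' `4 / (1/n_cases + 1/n_controls)`. Pleiotropic effects are added to the
#' outcome means per the configured regime. A configurable fraction of
#' instruments is omitted from the outcome table; a fraction of those get a
#' high-LD proxy row whose outcome effect is attenuated by `sqrt(r2)`.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure`, `outcome` (canonical summary tables),
#'   `proxies` (LD proxy table or `NULL`), and `truth` (per-SNP `gamma`,
#'   `alpha`, `pleiotropic`, `maf`, global `theta`, and the missing/proxied
#'   rsids).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  k <- cfg$k
  rsid <- sprintf("rs%07d", sample.int(9e6, k))
  maf <- stats::runif(k, cfg$maf_range[1], cfg$maf_range[2])
  het <- 2 * maf * (1 - maf)

  se_x <- 1 / sqrt(het * cfg$n_exposure)
  # True effect magnitudes, in discovery z-score units, follow a shifted
  # exponential floored at the genome-wide threshold plus a 3-SD sampling
  # margin: an instrument panel is by construction made of discovered,
  # significant SNPs. The exponential mean is set by the joint-R2 budget
  # E[z^2] = n r2 / k; when the budget cannot support the floor the floor
  # shrinks to the equal-effects limit.
  z_sig <- stats::qnorm(2.5e-8, lower.tail = FALSE)
  t_z2 <- cfg$n_exposure * cfg$r2_target / k
  zf <- z_sig + 3
  if (zf^2 >= t_z2) zf <- sqrt(t_z2)
  m_exp <- max(0, (-zf + sqrt(max(0, 2 * t_z2 - zf^2))) / 2)
  z_mag <- zf + if (m_exp > 0) stats::rexp(k, rate = 1 / m_exp) else numeric(k)
  z_true <- z_mag * sample(c(-1, 1), k, replace = TRUE)
  gamma <- z_true * se_x
  gamma <- gamma * sqrt(cfg$r2_target / sum(het * gamma^2))  # exact joint R2
  beta_x <- stats::rnorm(k, gamma, se_x)

  n_pleio <- round(cfg$pi_pleio * k)
  pleio <- rep(FALSE, k)
  alpha <- numeric(k)
  if (cfg$pleiotropy_mode != "none" && n_pleio > 0) {
    idx <- sample.int(k, n_pleio)
    pleio[idx] <- TRUE
    alpha[idx] <- switch(cfg$pleiotropy_mode,
      balanced = stats::rnorm(n_pleio, 0, cfg$sigma_alpha),
      directional = stats::rnorm(n_pleio, cfg$mu_alpha, cfg$sigma_alpha),
      inside_violating = cfg$mu_alpha + cfg$q_inside * gamma[idx] +
        stats::rnorm(n_pleio, 0, cfg$sigma_alpha))
  }

  n_eff <- 4 / (1 / cfg$n_cases + 1 / cfg$n_controls)
  se_y <- 1 / sqrt(het * n_eff)
  mu_y <- cfg$theta * gamma + alpha
  beta_y <- stats::rnorm(k, mu_y, se_y)

  ap <- sim_allele_pairs[sample.int(nrow(sim_allele_pairs), k, replace = TRUE), , drop = FALSE]
  base <- data.frame(rsid = rsid,
                     chr = as.character(sample.int(22, k, replace = TRUE)),
                     pos = sample.int(2e8, k),
                     ea = ap[, 1], oa = ap[, 2], eaf = maf,
                     stringsAsFactors = FALSE)
  exposure <- base
  exposure$beta <- beta_x; exposure$se <- se_x
  exposure$pval <- pmax(two_sided_p(beta_x, se_x), 1e-300)
  exposure$n <- cfg$n_exposure

  n_missing <- round(cfg$missing_frac * k)
  miss_idx <- if (n_missing > 0) sample.int(k, n_missing) else integer()
  n_proxy <- round(cfg$proxy_frac * n_missing)
  proxy_idx <- if (n_proxy > 0) miss_idx[seq_len(n_proxy)] else integer()

  outcome <- base[setdiff(seq_len(k), miss_idx), , drop = FALSE]
  outcome$beta <- beta_y[setdiff(seq_len(k), miss_idx)]
  outcome$se <- se_y[setdiff(seq_len(k), miss_idx)]
  outcome$pval <- pmax(two_sided_p(outcome$beta, outcome$se), 1e-300)
  outcome$n <- cfg$n_cases + cfg$n_controls

  proxies <- NULL
  if (length(proxy_idx)) {
    r2p <- stats::runif(length(proxy_idx), cfg$r2_proxy_range[1], cfg$r2_proxy_range[2])
    prs <- sprintf("rs%07d", 9e6 + sample.int(9e5, length(proxy_idx)))
    # proxy outcome effect attenuates toward zero by sqrt(r2)
    pb <- stats::rnorm(length(proxy_idx), sqrt(r2p) * mu_y[proxy_idx], se_y[proxy_idx])
    prows <- base[proxy_idx, , drop = FALSE]
    prows$rsid <- prs
    prows$pos <- prows$pos + sample.int(5e4, length(proxy_idx))
    prows$beta <- pb; prows$se <- se_y[proxy_idx]
    prows$pval <- two_sided_p(pb, se_y[proxy_idx])
    prows$n <- cfg$n_cases + cfg$n_controls
    outcome <- rbind(outcome, prows)
    proxies <- data.frame(target = rsid[proxy_idx], proxy = prs, r2 = r2p,
                          target_ea = base$ea[proxy_idx], proxy_ea = prows$ea,
                          target_oa = base$oa[proxy_idx], proxy_oa = prows$oa,
                          stringsAsFactors = FALSE)
  }
  rownames(outcome) <- NULL

  truth <- list(rsid = rsid, gamma = gamma, alpha = alpha, pleiotropic = pleio,
                maf = maf, theta = cfg$theta,
                missing = rsid[miss_idx], proxied = rsid[proxy_idx],
                r2_realized = sum(het * gamma^2))
  list(exposure = exposure, outcome = outcome, proxies = proxies, truth = truth)
}

#' Simulate a secondary-phenotype exclusion list
#'
#' Samples a fraction of instrument rsids as "associated with other
#' traits", optionally enriched for truly pleiotropic instruments by a
#' sampling-weight multiplier (an infinite multiplier restricts the list to
#' pleiotropic instruments).
#'
#' @param truth `truth` component of [simulate_dataset()].
#' @param frac Fraction of instruments to list.
#' @param seed Mandatory RNG seed.
#' @param enrichment Sampling-weight multiplier for pleiotropic instruments
#'   (default 1 = unenriched).
#' @return Data.frame with `rsid` and `trait` columns, the exclusion-list
#'   input format.
#' @export
simulate_secondary_list <- function(truth, frac, seed, enrichment = 1) {
  stopifnot(frac >= 0, frac <= 1)
  if (missing(seed)) stopf("simulate_secondary_list: an explicit seed is required")
  set.seed(seed)
  k <- length(truth$rsid)
  n <- round(frac * k)
  if (n == 0) return(data.frame(rsid = character(), trait = character(), stringsAsFactors = FALSE))
  if (is.infinite(enrichment)) {
    pool <- truth$rsid[truth$pleiotropic]
    picked <- sample(pool, min(n, length(pool)))
  } else {
    wgt <- ifelse(truth$pleiotropic, enrichment, 1)
    picked <- sample(truth$rsid, n, prob = wgt)
  }
  data.frame(rsid = picked, trait = "secondary_phenotype", stringsAsFactors = FALSE)
}

#' Simulate a multivariable MR input table
#'
#' Instruments carry effects on `m` exposures (independent normal draws per
#' exposure, observed with sampling noise); the outcome beta is the sum of
#' the true direct effects times the true exposure effects plus noise.
#'
#' @param k Instrument count.
#' @param effects Named numeric vector of true direct effects (log-odds per
#'   exposure unit); names become the exposure labels.
#' @param se_exposure,se_outcome Sampling SDs of the observed betas.
#' @param gamma_sd SD of the true per-SNP exposure effects.
#' @param seed Mandatory RNG seed.
#' @return List with `data` (MVMR input data.frame) and `truth`
#'   (the `effects` vector and per-SNP true exposure effects).
#' @export
simulate_mv_dataset <- function(k, effects, se_exposure = 0.01, se_outcome = 0.01,
                                gamma_sd = 0.05, seed) {
  if (missing(seed)) stopf("simulate_mv_dataset: an explicit seed is required")
  m <- length(effects)
  stopifnot(m >= 1, !is.null(names(effects)), k > m)
  set.seed(seed)
  G <- matrix(stats::rnorm(k * m, 0, gamma_sd), k, m)
  Bx <- G + matrix(stats::rnorm(k * m, 0, se_exposure), k, m)
  by <- as.numeric(G %*% effects) + stats::rnorm(k, 0, se_outcome)
  d <- data.frame(rsid = sprintf("rs%07d", seq_len(k)), stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    d[[paste0("beta_", names(effects)[j])]] <- Bx[, j]
    d[[paste0("se_", names(effects)[j])]] <- se_exposure
  }
  d$beta_outcome <- by
  d$se_outcome <- se_outcome
  list(data = d, truth = list(effects = effects, gamma = G))
}

#' Write a simulated dataset to disk in the pipeline's input formats
#'
#' @param sim Result of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written
#'   (`exposure.tsv`, `outcome.tsv`, optionally `proxies.tsv`,
#'   `truth.json`).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(exposure = file.path(dir, "exposure.tsv"),
             outcome = file.path(dir, "outcome.tsv"))
  utils::write.table(sim$exposure, paths["exposure"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$outcome, paths["outcome"], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$proxies)) {
    paths["proxies"] <- file.path(dir, "proxies.tsv")
    utils::write.table(sim$proxies, paths["proxies"], sep = "\t", quote = FALSE, row.names = FALSE)
  }
  paths["truth"] <- file.path(dir, "truth.json")
  jsonlite::write_json(sim$truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
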