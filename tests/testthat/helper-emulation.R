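# Study-configuration emulation: a 378-SNP instrument panel jointly
# explaining 2.3% of exposure variance (n = 1,232,091), a 14,361/43,923
# case-control outcome, true causal log-OR ln(1.32), 34 instruments missing
# from the outcome with 23 recoverable through high-LD proxies, and three
# instruments carrying large balanced pleiotropic offsets (the outlier
# regime the pipeline's PRESSO stage is meant to catch).
make_study_emulation <- function(seed) {
  cfg <- sim_config(k = 378, missing_frac = 34 / 378, proxy_frac = 23 / 34,
                    seed = seed)
  sim <- simulate_dataset(cfg)
  set.seed(seed + 1)
  present <- sim$outcome$rsid[sim$outcome$rsid %in% sim$truth$rsid]
  spiked <- sample(present, 3)
  idx <- match(spiked, sim$outcome$rsid)
  offs <- c(1, -1, 1) * 8 * sim$outcome$se[idx]   # balanced large offsets
  sim$outcome$beta[idx] <- sim$outcome$beta[idx] + offs
  sim$outcome$pval[idx] <- pmax(2 * pnorm(-abs(sim$outcome$beta[idx] / sim$outcome$se[idx])), 1e-300)
  secondary <- simulate_secondary_list(sim$truth, frac = 60 / 378, seed = seed + 2)
  list(sim = sim, spiked = spiked, secondary = secondary, cfg = cfg)
}

harmonize_emulation <- function(em) {
  sel <- select_genomewide(em$sim$exposure)
  missing <- setdiff(sel$rsid, em$sim$outcome$rsid)
  proxies <- apply_proxies(missing, em$sim$proxies, em$sim$outcome)
  harmonize_instruments(sel, em$sim$outcome, proxies)
}
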