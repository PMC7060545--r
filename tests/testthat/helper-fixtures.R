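# Fixture builders shared across test files.

make_assoc <- function(rsid = "rs1", ea = "A", oa = "G", eaf = 0.3,
                       beta = 0.02, se = 0.003, pval = 1e-10, n = 1000,
                       chr = "1", pos = 1000) {
  data.frame(rsid = rsid, chr = chr, pos = pos, ea = ea, oa = oa, eaf = eaf,
             beta = beta, se = se, pval = pval, n = n, stringsAsFactors = FALSE)
}

# instruments straight from ratio-space quantities: beta_exposure = 1 with a
# negligible exposure SE, so theta_j = beta_outcome and se_j = se_outcome
make_instruments <- function(theta, se, rsid = sprintf("rs%d", seq_along(theta))) {
  data.frame(rsid = rsid, beta_exposure = 1, se_exposure = 1e-8,
             beta_outcome = theta, se_outcome = se,
             eaf_exposure = NA_real_, eaf_outcome = NA_real_,
             proxy_of = NA_character_, palindromic = FALSE, flipped = FALSE,
             stringsAsFactors = FALSE)
}

random_instruments <- function(k, seed, theta = 0.3, bx_sd = 0.05,
                               se_x = 0.005, se_y = 0.05, alpha = 0) {
  set.seed(seed)
  bx_true <- rnorm(k, 0.1, bx_sd)
  data.frame(rsid = sprintf("rs%d", seq_len(k)),
             beta_exposure = rnorm(k, bx_true, se_x), se_exposure = se_x,
             beta_outcome = rnorm(k, theta * bx_true + alpha, se_y), se_outcome = se_y,
             eaf_exposure = NA_real_, eaf_outcome = NA_real_,
             proxy_of = NA_character_, palindromic = FALSE, flipped = FALSE,
             stringsAsFactors = FALSE)
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Generate-harmonize shortcut for simulation-based tests (no file round-trip).
sim_instruments <- function(cfg) {
  sim <- simulate_dataset(cfg)
  sel <- select_genomewide(sim$exposure)
  missing <- setdiff(sel$rsid, sim$outcome$rsid)
  proxies <- if (!is.null(sim$proxies) && length(missing))
    apply_proxies(missing, sim$proxies, sim$outcome) else NULL
  list(instruments = harmonize_instruments(sel, sim$outcome, proxies), sim = sim)
}
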