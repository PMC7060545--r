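default_config <- list(
  p_threshold = 5e-8,
  r2_min = 0.9,
  palindrome_policy = "drop",
  eaf_threshold = 0.42,
  estimators = c("ivw", "weighted_median", "egger", "presso"),
  presso = list(n_sim = NULL, alpha = 0.05, seed = NULL),
  weighted_median = list(n_boot = 10000, seed = NULL),
  exposure = list(path = NULL, column_map = NULL),
  outcome = list(path = NULL, column_map = NULL),
  proxy_table = NULL,
  exclusion_list = NULL,
  mvmr_table = NULL,
  output_dir = NULL
)

merge_defaults <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]] <- merge_defaults(cfg[[nm]], defaults[[nm]])
  }
  cfg
}

#' Validate an analysis configuration
#'
#' Reads a YAML or JSON configuration (or takes a list), fills defaults,
#' and collects every violation in one pass rather than failing fast.
#'
#' @param x Path to a `.yaml`/`.yml`/`.json` config file, or a named list.
#' @return List with `config` (fully defaulted, `NULL` when invalid) and
#'   `errors` (character vector of violations, empty when valid).
#' @export
validate_config <- function(x) {
  if (is.character(x)) {
    if (!file.exists(x)) return(list(config = NULL, errors = sprintf("config file not found: %s", x)))
    x <- tryCatch(
      if (grepl("\\.json$", x, ignore.case = TRUE)) jsonlite::read_json(x, simplifyVector = TRUE)
      else yaml::read_yaml(x),
      error = function(e) e)
    if (inherits(x, "error"))
      return(list(config = NULL, errors = sprintf("config parse error: %s", conditionMessage(x))))
  }
  cfg <- merge_defaults(as.list(x), default_config)
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(!is.null(cfg$exposure$path), "exposure.path is required")
  chk(!is.null(cfg$outcome$path), "outcome.path is required")
  for (p in c(cfg$exposure$path, cfg$outcome$path, cfg$proxy_table,
              cfg$exclusion_list, cfg$mvmr_table))
    if (!is.null(p) && !file.exists(p)) errs <- c(errs, sprintf("file not found: %s", p))
  chk(is.numeric(cfg$p_threshold) && cfg$p_threshold > 0 && cfg$p_threshold < 1,
      "p_threshold not in (0,1)")
  chk(is.numeric(cfg$r2_min) && cfg$r2_min > 0 && cfg$r2_min <= 1, "r2_min not in (0,1]")
  chk(cfg$palindrome_policy %in% c("drop", "infer_by_eaf", "keep"),
      "palindrome_policy must be drop, infer_by_eaf or keep")
  chk(all(cfg$estimators %in% c("ivw", "weighted_median", "egger", "presso")),
      "unknown estimator in estimator list")
  chk(is.numeric(cfg$presso$alpha) && cfg$presso$alpha > 0 && cfg$presso$alpha < 1,
      "presso.alpha not in (0,1)")
  if ("presso" %in% cfg$estimators)
    chk(!is.null(cfg$presso$seed), "presso.seed is required when presso is requested")
  if ("weighted_median" %in% cfg$estimators)
    chk(!is.null(cfg$weighted_median$seed),
        "weighted_median.seed is required when weighted_median is requested")
  list(config = if (length(errs)) NULL else cfg, errors = errs)
}

#' Run the full two-sample MR analysis
#'
#' Executes, in order: read summary tables, genome-wide significance filter,
#' outcome lookup, LD-proxy substitution, allele harmonization, the
#' requested estimators (random-effects IVW primary, weighted median,
#' MR-Egger with intercept test, MR-PRESSO with outlier-corrected
#' re-estimation), and the optional sensitivity analyses
#' (secondary-phenotype-excluded IVW, multivariable IVW).
#'
#' @param cfg A validated config list (see [validate_config()]).
#' @return List of class `mr_report`: `accounting` (requested / missing /
#'   proxied / used), `estimates` (named `mr_estimate`/`mr_egger` objects),
#'   `egger`, `presso`, `sensitivity`, and a `provenance` block (config
#'   hash, seeds, package version) sufficient to re-run bit-identically.
#' @export
run_analysis <- function(cfg) {
  v <- validate_config(cfg)
  if (length(v$errors)) stopf("invalid configuration: %s", paste(v$errors, collapse = "; "))
  cfg <- v$config
  stage <- function(s, expr) {
    message(sprintf("[stage] %s", s))
    tryCatch(expr, error = function(e) stopf("stage '%s' failed: %s", s, conditionMessage(e)))
  }

  exposure <- stage("read exposure", read_summary_table(cfg$exposure$path, cfg$exposure$column_map))
  outcome <- stage("read outcome", read_summary_table(cfg$outcome$path, cfg$outcome$column_map))
  sel <- stage("genome-wide filter", select_genomewide(exposure, cfg$p_threshold))
  message(sprintf("[stage] selected %d of %d exposure SNPs at p < %g",
                  nrow(sel), nrow(exposure), cfg$p_threshold))
  missing <- setdiff(sel$rsid, outcome$rsid)
  proxies <- NULL
  if (!is.null(cfg$proxy_table) && length(missing)) {
    ld <- stage("read LD table", read_ld_table(cfg$proxy_table))
    proxies <- stage("proxy substitution", apply_proxies(missing, ld, outcome, cfg$r2_min))
  }
  n_proxied <- if (is.null(proxies) || is.null(proxies$substitutions)) 0L else nrow(proxies$substitutions)
  inst <- stage("harmonization",
                harmonize_instruments(sel, outcome, proxies,
                                      cfg$palindrome_policy, cfg$eaf_threshold))
  if (nrow(inst) == 0) stopf("empty instrument set after selection/harmonization")
  accounting <- list(requested = nrow(sel), missing = length(missing),
                     proxied = n_proxied, used = nrow(inst))
  message(sprintf("[stage] instruments: %d requested / %d missing / %d proxied / %d used",
                  accounting$requested, accounting$missing, accounting$proxied, accounting$used))

  estimates <- list(); egger <- NULL; presso <- NULL
  if ("ivw" %in% cfg$estimators)
    estimates$ivw <- stage("IVW", mr_ivw(inst, model = "random"))
  if ("weighted_median" %in% cfg$estimators)
    estimates$weighted_median <- stage("weighted median",
      mr_weighted_median(inst, n_boot = cfg$weighted_median$n_boot,
                         seed = cfg$weighted_median$seed))
  if ("egger" %in% cfg$estimators) {
    egger <- stage("MR-Egger", mr_egger(inst))
    estimates$egger <- egger$slope
  }
  if ("presso" %in% cfg$estimators) {
    presso <- stage("MR-PRESSO",
      mr_presso(inst, n_sim = cfg$presso$n_sim, alpha = cfg$presso$alpha,
                seed = cfg$presso$seed))
    estimates$presso_corrected <- presso$corrected
  }

  sensitivity <- list()
  if (!is.null(cfg$exclusion_list)) {
    excl <- utils::read.table(cfg$exclusion_list, header = TRUE,
                              sep = sniff_delim(cfg$exclusion_list),
                              stringsAsFactors = FALSE)
    kept <- stage("secondary-phenotype exclusion", exclude_secondary_phenotypes(inst, excl))
    est <- stage("IVW (secondary excluded)", mr_ivw(kept, model = "random"))
    est$method <- "ivw_secondary_excluded"
    sensitivity$secondary_excluded <- est
    sensitivity$n_excluded <- nrow(inst) - nrow(kept)
  }
  if (!is.null(cfg$mvmr_table)) {
    mvdat <- stage("read MVMR table", read_mvmr_table(cfg$mvmr_table))
    sensitivity$mvmr <- stage("multivariable IVW", mr_mvivw(mvdat))
  }

  report <- structure(list(
    accounting = accounting,
    estimates = estimates,
    egger = egger,
    presso = presso,
    sensitivity = sensitivity,
    instruments = inst,
    provenance = list(
      config_hash = fnv1a32(jsonlite::toJSON(cfg[setdiff(names(cfg), "output_dir")],
                                             auto_unbox = TRUE, null = "null", digits = NA)),
      seeds = list(presso = cfg$presso$seed, weighted_median = cfg$weighted_median$seed),
      package_version = as.character(utils::packageVersion("mrpipe")))),
    class = "mr_report")
  if (!is.null(cfg$output_dir)) write_report(report, cfg$output_dir)
  report
}

estimate_record <- function(est, egger = NULL) {
  data.frame(method = est$method, n_snp = est$k, beta = est$beta, se = est$se,
             or = est$or, or_lo95 = est$or_low, or_hi95 = est$or_high,
             pval = est$pval, q_stat = est$q_stat, q_pval = est$q_pval,
             egger_intercept = if (is.null(egger)) NA_real_ else egger$intercept,
             egger_intercept_p = if (is.null(egger)) NA_real_ else egger$intercept_pval,
             stringsAsFactors = FALSE)
}

#' Collect a report's estimates into one results table
#'
#' @param report An `mr_report`.
#' @return Data.frame with one row per estimate (primary, weighted median,
#'   Egger slope, PRESSO-corrected, sensitivity rows), full precision.
#' @export
report_table <- function(report) {
  rows <- list()
  for (nm in names(report$estimates)) {
    rows[[nm]] <- estimate_record(report$estimates[[nm]],
                                  if (nm == "egger") report$egger else NULL)
  }
  if (!is.null(report$sensitivity$secondary_excluded))
    rows$secondary_excluded <- estimate_record(report$sensitivity$secondary_excluded)
  if (!is.null(report$sensitivity$mvmr))
    for (nm in names(report$sensitivity$mvmr))
      rows[[paste0("mvmr_", nm)]] <- estimate_record(report$sensitivity$mvmr[[nm]])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an analysis report to disk
#'
#' Emits `report.tsv` (formatted forest-style table: two-decimal odds
#' ratios, scientific p-values), `report.json` (full precision, includes
#' accounting and provenance), and `outliers.tsv` (per-SNP MR-PRESSO
#' outlier table) when PRESSO was run.
#'
#' @param report An `mr_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- report_table(report)
  fmt <- tab
  for (cl in c("beta", "se", "q_stat")) fmt[[cl]] <- sprintf("%.4f", tab[[cl]])
  for (cl in c("or", "or_lo95", "or_hi95")) fmt[[cl]] <- sprintf("%.2f", tab[[cl]])
  for (cl in c("pval", "q_pval", "egger_intercept_p")) fmt[[cl]] <- sprintf("%.2e", tab[[cl]])
  fmt$egger_intercept <- sprintf("%.4f", tab$egger_intercept)
  paths <- c(tsv = file.path(dir, "report.tsv"), json = file.path(dir, "report.json"))
  utils::write.table(fmt, paths["tsv"], sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  json <- list(accounting = report$accounting, results = tab,
               presso = if (!is.null(report$presso))
                 list(rss_obs = report$presso$rss_obs, p_global = report$presso$p_global,
                      n_outliers = length(report$presso$outliers),
                      outliers = report$presso$outliers,
                      n_sim = report$presso$n_sim, alpha = report$presso$alpha),
               provenance = report$provenance)
  jsonlite::write_json(json, paths["json"], auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(report$presso)) {
    paths["outliers"] <- file.path(dir, "outliers.tsv")
    utils::write.table(report$presso$per_snp, paths["outliers"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}

#' @export
print.mr_report <- function(x, ...) {
  a <- x$accounting
  cat(sprintf("mr_report: %d requested / %d missing / %d proxied / %d used\n",
              a$requested, a$missing, a$proxied, a$used))
  for (e in x$estimates) print(e)
  if (!is.null(x$egger))
    cat(sprintf("  Egger intercept p = %.3g\n", x$egger$intercept_pval))
  if (!is.null(x$presso))
    cat(sprintf("  PRESSO global p = %.3g, %d outlier(s)\n",
                x$presso$p_global, length(x$presso$outliers)))
  invisible(x)
}
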