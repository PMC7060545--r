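#' Canonical summary-statistics columns
#'
#' The canonical column names used throughout the package for GWAS
#' summary-statistics tables: `rsid`, `chr`, `pos`, `ea` (effect allele),
#' `oa` (other allele), `eaf` (effect-allele frequency), `beta`, `se`,
#' `pval`, `n`.
#'
#' @format Character vector of the ten canonical field names.
#' @export
summary_fields <- c("rsid", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")

mandatory_fields <- c("rsid", "ea", "oa", "beta", "se", "pval")

sniff_delim <- function(path) {
  line <- readLines(path, n = 1L)
  if (grepl("\t", line, fixed = TRUE)) "\t" else ","
}

#' Read a GWAS summary-statistics table
#'
#' Reads a headered TSV or CSV of per-SNP association statistics into the
#' canonical column layout. Rows violating basic invariants (non-positive or
#' non-finite standard error, p-value outside (0, 1], missing rsid or
#' alleles, identical effect and other alleles, effect-allele frequency
#' outside \[0, 1\]) are dropped with a warning. Duplicated rsids keep the
#' row with the smallest p-value.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical field names
#'   (see [summary_fields]) to column names in the file, e.g.
#'   `c(rsid = "SNP", beta = "Effect")`. Canonical names present in the
#'   header are picked up automatically; fields absent from the map and the
#'   header are filled with `NA` when optional.
#' @param delim Field delimiter; sniffed from the header line when `NULL`.
#' @return A data.frame with the canonical columns; alleles upper-cased.
#'   The number of dropped rows is attached as attribute `"dropped"`.
#' @export
read_summary_table <- function(path, column_map = NULL, delim = NULL) {
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  delim <- delim %||% sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim, quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE,
                           check.names = FALSE)
  map <- stats::setNames(summary_fields, summary_fields)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), summary_fields)
    if (length(bad)) stopf("unknown field(s) in column_map: %s", paste(bad, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  for (f in mandatory_fields) {
    if (!map[[f]] %in% names(raw))
      stopf("mandatory column '%s' (field '%s') not found in %s", map[[f]], f, path)
  }
  out <- data.frame(rsid = as.character(raw[[map[["rsid"]]]]), stringsAsFactors = FALSE)
  pick_num <- function(f) {
    if (map[[f]] %in% names(raw)) suppressWarnings(as.numeric(raw[[map[[f]]]])) else rep(NA_real_, nrow(raw))
  }
  out$chr  <- if (map[["chr"]] %in% names(raw)) as.character(raw[[map[["chr"]]]]) else NA_character_
  out$pos  <- pick_num("pos")
  out$ea   <- toupper(as.character(raw[[map[["ea"]]]]))
  out$oa   <- toupper(as.character(raw[[map[["oa"]]]]))
  out$eaf  <- pick_num("eaf")
  out$beta <- pick_num("beta")
  out$se   <- pick_num("se")
  out$pval <- pick_num("pval")
  out$n    <- pick_num("n")

  ok <- !is.na(out$rsid) & nzchar(out$rsid) &
    nzchar(out$ea) & nzchar(out$oa) & out$ea != out$oa &
    is.finite(out$beta) & is.finite(out$se) & out$se > 0 &
    is.finite(out$pval) & out$pval > 0 & out$pval <= 1 &
    (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1))
  dropped <- sum(!ok)
  if (dropped > 0)
    warnf("%d of %d rows dropped for invariant violations in %s", dropped, nrow(out), basename(path))
  out <- out[ok, , drop = FALSE]

  if (anyDuplicated(out$rsid)) {
    ndup <- sum(duplicated(out$rsid))
    warnf("%d duplicated rsid(s) in %s: keeping smallest p-value", ndup, basename(path))
    out <- out[order(out$pval), , drop = FALSE]
    out <- out[!duplicated(out$rsid), , drop = FALSE]
    dropped <- dropped + ndup
  }
  rownames(out) <- NULL
  message(sprintf("read %d records from %s (%d dropped)", nrow(out), basename(path), dropped))
  attr(out, "dropped") <- dropped
  out
}

empty_instruments <- function() {
  data.frame(rsid = character(), beta_exposure = numeric(), se_exposure = numeric(),
             beta_outcome = numeric(), se_outcome = numeric(),
             eaf_exposure = numeric(), eaf_outcome = numeric(),
             proxy_of = character(), palindromic = logical(), flipped = logical(),
             stringsAsFactors = FALSE)
}

#' Harmonize one exposure/outcome SNP pair onto a shared effect allele
#'
#' Aligns the outcome association to the exposure's effect allele: swapped
#' allele labels negate the outcome beta (and complement the reported
#' frequency), strand flips (A<->T, C<->G relabelling) are resolved by
#' complementing, and palindromic (A/T, C/G) variants are handled according
#' to `palindrome_policy`.
#'
#' @param exp,out Single records (one-row data.frame or named list) with the
#'   canonical fields of [read_summary_table()]; `exp$rsid` must equal
#'   `out$rsid`.
#' @param palindrome_policy `"drop"` rejects palindromic variants (default:
#'   without frequency information their strand is unresolvable);
#'   `"infer_by_eaf"` aligns by effect-allele-frequency concordance,
#'   provided both frequencies are outside
#'   `[eaf_threshold, 1 - eaf_threshold]`; `"keep"` aligns by allele label
#'   only.
#' @param eaf_threshold Ambiguity band half-width for `"infer_by_eaf"`.
#' @return A list with `instrument` (one-row data.frame, or `NULL` on
#'   rejection) and `reason` (`NA` or the rejection reason).
#' @export
harmonize_pair <- function(exp, out,
                           palindrome_policy = c("drop", "infer_by_eaf", "keep"),
                           eaf_threshold = 0.42) {
  palindrome_policy <- match.arg(palindrome_policy)
  exp <- as.list(exp); out <- as.list(out)
  if (!identical(as.character(exp$rsid), as.character(out$rsid)))
    stopf("harmonize_pair: rsid mismatch (%s vs %s)", exp$rsid, out$rsid)
  e_ea <- toupper(exp$ea); e_oa <- toupper(exp$oa)
  o_ea <- toupper(out$ea); o_oa <- toupper(out$oa)
  beta_y <- out$beta; eaf_y <- out$eaf %||% NA_real_
  if (is.null(eaf_y) || length(eaf_y) == 0) eaf_y <- NA_real_
  eaf_x <- exp$eaf %||% NA_real_
  if (is.null(eaf_x) || length(eaf_x) == 0) eaf_x <- NA_real_
  flipped <- FALSE
  pal <- is_palindromic(e_ea, e_oa)

  reject <- function(reason) list(instrument = NULL, reason = reason)
  same_set <- function(a1, a2) setequal(c(a1[1], a1[2]), c(a2[1], a2[2]))

  if (pal) {
    if (palindrome_policy == "drop") return(reject("palindromic"))
    if (!same_set(c(o_ea, o_oa), c(e_ea, e_oa))) return(reject("allele mismatch"))
    if (o_ea != e_ea) {  # label swap first
      beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- !flipped
    }
    if (palindrome_policy == "infer_by_eaf") {
      thr <- eaf_threshold
      informative <- function(f) is.finite(f) && (f < thr || f > 1 - thr)
      if (!informative(eaf_x) || !informative(eaf_y))
        return(reject("ambiguous palindrome"))
      if ((eaf_x < 0.5) != (eaf_y < 0.5)) {  # frequencies discordant: strand flip
        beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- !flipped
      }
    }
  } else {
    if (same_set(c(o_ea, o_oa), c(e_ea, e_oa))) {
      if (o_ea != e_ea) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- !flipped }
    } else if (same_set(allele_complement(c(o_ea, o_oa)), c(e_ea, e_oa))) {
      o_ea <- allele_complement(o_ea)  # strand flip: relabel, frequency unchanged
      if (o_ea != e_ea) { beta_y <- -beta_y; eaf_y <- 1 - eaf_y; flipped <- !flipped }
    } else {
      return(reject("allele mismatch"))
    }
  }

  inst <- data.frame(
    rsid = as.character(exp$rsid),
    beta_exposure = exp$beta, se_exposure = exp$se,
    beta_outcome = beta_y, se_outcome = out$se,
    eaf_exposure = eaf_x, eaf_outcome = eaf_y,
    proxy_of = NA_character_, palindromic = pal, flipped = flipped,
    stringsAsFactors = FALSE)
  list(instrument = inst, reason = NA_character_)
}

#' Substitute LD proxies for instruments missing from the outcome data
#'
#' For each missing instrument, the available proxy with the highest LD
#' r-squared strictly above `r2_min` is taken from the outcome table and its
#' alleles are re-keyed to the target's alleles through the explicit allele
#' correspondence columns of the LD table.
#'
#' @param missing Character vector of instrument rsids absent from the
#'   outcome table.
#' @param ld LD proxy table: data.frame with columns `target`, `proxy`,
#'   `r2`, `target_ea`, `proxy_ea`, `target_oa`, `proxy_oa`.
#' @param outcome Outcome summary-statistics data.frame (canonical columns).
#' @param r2_min Minimum LD r-squared (exclusive); default 0.9.
#' @return List with `substitutions` (canonical association rows keyed to
#'   the target's alleles, plus `target_rsid`, `proxy_rsid`, `r2`) and
#'   `unresolved` (targets with no qualifying proxy).
#' @export
apply_proxies <- function(missing, ld, outcome, r2_min = 0.9) {
  stopifnot(r2_min > 0, r2_min <= 1)
  subs <- list(); unresolved <- character()
  if (length(missing) == 0)
    return(list(substitutions = NULL, unresolved = unresolved))
  for (t in missing) {
    cand <- ld[ld$target == t & ld$r2 > r2_min & ld$proxy %in% outcome$rsid, , drop = FALSE]
    found <- FALSE
    if (nrow(cand) > 0) {
      cand <- cand[order(-cand$r2), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        row <- cand[i, ]
        o <- outcome[outcome$rsid == row$proxy, , drop = FALSE][1, ]
        p_ea <- toupper(row$proxy_ea); p_oa <- toupper(row$proxy_oa)
        o_ea <- toupper(o$ea); o_oa <- toupper(o$oa)
        # match the outcome record's alleles to the correspondence, allowing
        # a strand-complemented representation
        if (setequal(c(o_ea, o_oa), c(p_ea, p_oa))) {
          # as labelled
        } else if (setequal(allele_complement(c(o_ea, o_oa)), c(p_ea, p_oa))) {
          o_ea <- allele_complement(o_ea); o_oa <- allele_complement(o_oa)
        } else next
        new_ea <- if (o_ea == p_ea) toupper(row$target_ea) else toupper(row$target_oa)
        new_oa <- if (o_ea == p_ea) toupper(row$target_oa) else toupper(row$target_ea)
        sub <- o
        sub$ea <- new_ea; sub$oa <- new_oa
        sub$target_rsid <- t; sub$proxy_rsid <- o$rsid; sub$r2 <- row$r2
        subs[[length(subs) + 1L]] <- sub
        found <- TRUE
        break
      }
    }
    if (!found) unresolved <- c(unresolved, t)
  }
  if (length(unresolved))
    message(sprintf("%d of %d missing instruments had no qualifying proxy (r2 > %g)",
                    length(unresolved), length(missing), r2_min))
  list(substitutions = if (length(subs)) do.call(rbind, subs) else NULL,
       unresolved = unresolved)
}

#' Harmonize an instrument set against an outcome table
#'
#' Pairs each selected exposure instrument with its outcome record (or an
#' LD-proxy substitution from [apply_proxies()]) and harmonizes each pair
#' with [harmonize_pair()].
#'
#' @param exposure,outcome Canonical summary-statistics data.frames.
#' @param proxies Optional result of [apply_proxies()].
#' @inheritParams harmonize_pair
#' @return Data.frame of harmonized instruments (columns `rsid`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`,
#'   `eaf_exposure`, `eaf_outcome`, `proxy_of`, `palindromic`, `flipped`);
#'   rejections attached as attribute `"rejections"` (rsid + reason).
#' @export
harmonize_instruments <- function(exposure, outcome, proxies = NULL,
                                  palindrome_policy = "drop", eaf_threshold = 0.42) {
  rows <- list(); rej <- list()
  direct <- intersect(exposure$rsid, outcome$rsid)
  for (r in direct) {
    h <- harmonize_pair(exposure[exposure$rsid == r, ][1, ],
                        outcome[outcome$rsid == r, ][1, ],
                        palindrome_policy, eaf_threshold)
    if (is.null(h$instrument)) rej[[length(rej) + 1L]] <- data.frame(rsid = r, reason = h$reason)
    else rows[[length(rows) + 1L]] <- h$instrument
  }
  if (!is.null(proxies) && !is.null(proxies$substitutions)) {
    ps <- proxies$substitutions
    for (i in seq_len(nrow(ps))) {
      t <- ps$target_rsid[i]
      if (!t %in% exposure$rsid) next
      erow <- exposure[exposure$rsid == t, ][1, ]
      orow <- ps[i, ]
      orow$rsid <- t  # pair on the instrument identity
      h <- harmonize_pair(erow, orow[, summary_fields], palindrome_policy, eaf_threshold)
      if (is.null(h$instrument)) {
        rej[[length(rej) + 1L]] <- data.frame(rsid = t, reason = h$reason)
      } else {
        h$instrument$rsid <- ps$proxy_rsid[i]
        h$instrument$proxy_of <- t
        rows[[length(rows) + 1L]] <- h$instrument
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_instruments()
  rownames(out) <- NULL
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else NULL
  out
}

#' Read an LD proxy table
#'
#' @param path Headered TSV with columns `target`, `proxy`, `r2`,
#'   `target_ea`, `proxy_ea`, `target_oa`, `proxy_oa`.
#' @return Data.frame with those columns, r2 validated to \[0, 1\].
#' @export
read_ld_table <- function(path) {
  ld <- utils::read.table(path, header = TRUE, sep = sniff_delim(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("target", "proxy", "r2", "target_ea", "proxy_ea", "target_oa", "proxy_oa")
  miss <- setdiff(need, names(ld))
  if (length(miss)) stopf("LD table missing column(s): %s", paste(miss, collapse = ", "))
  if (any(!is.finite(ld$r2) | ld$r2 < 0 | ld$r2 > 1)) stopf("LD table r2 outside [0,1]")
  ld
}
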