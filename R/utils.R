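#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Nucleotide complement for strand-flip resolution; non-ACGT characters
# pass through unchanged (indel codes are never complemented).
allele_complement <- function(x) chartr("ACGT", "TGCA", toupper(x))

is_palindromic <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  nchar(ea) == 1L & nchar(oa) == 1L & allele_complement(ea) == oa
}

# 32-bit FNV-1a over a string; used for config provenance hashes only.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor touches the low byte only
    # 32-bit modular multiply via 16-bit limbs (doubles stay exact)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31)) # printable hash; truncation is fine here
}

two_sided_p <- function(beta, se) 2 * stats::pnorm(-abs(beta / se))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
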