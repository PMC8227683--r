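#' @keywords internal
"_PACKAGE"

# Split a sequence string into a character vector of single bases.
seq_chars <- function(seq) {
  if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1L]] else as.character(seq)
}

collapse_chars <- function(x) paste(x, collapse = "")

#' Reverse complement of a nucleotide string
#'
#' Ambiguity codes are complemented where defined (IUPAC); characters
#' without a complement (e.g. `-`) are left untouched.
#'
#' @param seq A single nucleotide string.
#' @return The reverse-complemented string.
#' @export
revcomp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  x <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
              "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", seq)
  collapse_chars(rev(seq_chars(x)))
}

# Circular 0-based half-open slice of a sequence string.  `start` < `end`
# slices directly; start >= end wraps across the origin.
circular_slice <- function(seq, start, end, len = nchar(seq)) {
  if (start < end) {
    substr(seq, start + 1L, end)
  } else {
    paste0(substr(seq, start + 1L, len), substr(seq, 1L, end))
  }
}

# stable %||%
`%||%` <- function(a, b) if (is.null(a)) b else a

# safe lookup in a named character vector (or list) of qualifiers
qual_get <- function(q, key) {
  if (!is.null(q) && key %in% names(q)) q[[key]] else NULL
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# deterministic sub-seed derivation, kept within 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647)
}
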