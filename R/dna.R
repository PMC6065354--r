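# Low-level DNA helpers shared across modules.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N, case-insensitive).
#' @return Character vector of reverse complements, uppercase.
#' @examples
#' revcomp("ATGC")
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Validate a DNA string: uppercase A/C/G/T plus optionally N.
check_dna <- function(seq, allow_n = TRUE, what = "sequence") {
  if (!is.character(seq) || length(seq) != 1L || is.na(seq))
    stop(what, " must be a single character string", call. = FALSE)
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!grepl(pat, seq))
    stop(what, " contains non-DNA characters", call. = FALSE)
  invisible(seq)
}

# Does `base` (a concrete A/C/G/T) satisfy the IUPAC code `code`?
# A subject N never matches: ambiguity in the subject is not evidence.
iupac_base_match <- function(code, base) {
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("invalid IUPAC code: ", code, call. = FALSE)
  base %in% set
}

# Match an IUPAC pattern (character vector of codes) against a window of
# concrete subject bases. Vectorised over nothing; both inputs are short.
iupac_match <- function(pattern_chars, subject_chars) {
  if (length(pattern_chars) != length(subject_chars)) return(FALSE)
  for (i in seq_along(pattern_chars)) {
    if (!iupac_base_match(pattern_chars[i], subject_chars[i])) return(FALSE)
  }
  TRUE
}

# All 0-based start indices where the IUPAC pattern matches the subject
# (subject split into single characters).
iupac_find_all <- function(pattern, subject_chars) {
  pc <- strsplit(toupper(pattern), "")[[1]]
  k <- length(pc)
  n <- length(subject_chars)
  if (n < k) return(integer(0))
  hits <- integer(0)
  for (s in 0:(n - k)) {
    if (iupac_match(pc, subject_chars[(s + 1):(s + k)])) hits <- c(hits, s)
  }
  hits
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Translate one codon with the standard genetic code (via Biostrings).
codon_aa <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}
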