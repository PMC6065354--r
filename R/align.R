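# Semi-global read-to-amplicon alignment with explicit costs, and the
# read-level filters applied before variant counting.

#' Alignment cost parameters
#'
#' Linear (per-base) costs for the semi-global read-to-reference alignment:
#' mismatch 2, inserted base 3, deleted base 3, with read-level filters
#' requiring at least `length_fraction` of the read aligned and
#' `similarity_fraction` identity over the aligned columns.
#'
#' @param mismatch_cost,insertion_cost,deletion_cost Positive per-base costs.
#' @param length_fraction,similarity_fraction Filter fractions in (0, 1].
#' @return An object of class `alignment_params`.
#' @export
alignment_params <- function(mismatch_cost = 2, insertion_cost = 3,
                             deletion_cost = 3, length_fraction = 0.5,
                             similarity_fraction = 0.8) {
  if (any(c(mismatch_cost, insertion_cost, deletion_cost) <= 0))
    stop("costs must be positive", call. = FALSE)
  if (any(c(length_fraction, similarity_fraction) <= 0) ||
      any(c(length_fraction, similarity_fraction) > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  structure(list(mismatch_cost = mismatch_cost,
                 insertion_cost = insertion_cost,
                 deletion_cost = deletion_cost,
                 length_fraction = length_fraction,
                 similarity_fraction = similarity_fraction),
            class = "alignment_params")
}

#' Variant filter thresholds
#'
#' A variant (position, alternative base or deletion) is reported only when
#' coverage >= `min_coverage`, supporting count >= `min_count`, and frequency
#' >= `min_frequency_percent`. Sub-threshold observations are retained in the
#' raw counts but flagged unreported.
#'
#' @param min_coverage Minimum coverage at the position (default 10).
#' @param min_count Minimum supporting read count (default 2).
#' @param min_frequency_percent Minimum frequency in percent (default 0.5).
#' @return An object of class `variant_filter`.
#' @export
variant_filter <- function(min_coverage = 10L, min_count = 2L,
                           min_frequency_percent = 0.5) {
  if (min_coverage < 0 || min_count < 0)
    stop("thresholds must be non-negative", call. = FALSE)
  if (min_frequency_percent < 0 || min_frequency_percent > 100)
    stop("min_frequency_percent must lie in [0, 100]", call. = FALSE)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_count = as.integer(min_count),
                 min_frequency_percent = min_frequency_percent),
            class = "variant_filter")
}

#' Align reads to a reference amplicon
#'
#' Minimum-cost semi-global alignment: each read is aligned end-to-end against
#' an internal span of the reference, with no penalty for reference overhangs.
#' Cost = `mismatch_cost` x mismatches + `insertion_cost` x inserted bases +
#' `deletion_cost` x deleted bases. Cost ties are resolved in favour of
#' mismatches over gaps. Per-read filter flags follow `params`:
#' `aligned_fraction >= length_fraction` and `identity >= similarity_fraction`,
#' where identity is the fraction of alignment columns that match.
#'
#' @param reads Character vector of read sequences (A/C/G/T/N).
#' @param ref Reference amplicon sequence.
#' @param params An [alignment_params()].
#' @param read_id Optional read identifiers.
#' @return A data.frame of class `amplicon_alignments` with columns `read_id`,
#'   `cost`, `ref_start` (0-based), `ref_end` (exclusive), `cigar` (ops
#'   `=`/`X`/`I`/`D`), `n_match`, `n_mismatch`, `n_ins`, `n_del`,
#'   `aligned_fraction`, `identity`, `passed_filters`, `seq`.
#' @export
align_reads <- function(reads, ref, params = alignment_params(),
                        read_id = NULL) {
  ref <- toupper(ref)
  check_dna(ref, allow_n = TRUE, what = "ref")
  if (nchar(ref) == 0L) stop("ref must be non-empty", call. = FALSE)
  reads <- toupper(reads)
  if (length(reads) == 0L) stop("no reads supplied", call. = FALSE)
  if (!all(grepl("^[ACGTN]+$", reads)))
    stop("reads contain non-DNA characters", call. = FALSE)
  if (is.null(read_id)) read_id <- paste0("read", seq_along(reads))
  res <- .align_reads_cpp(reads, ref, as.integer(params$mismatch_cost),
                          as.integer(params$insertion_cost),
                          as.integer(params$deletion_cost))
  read_len <- nchar(reads)
  aligned <- res$n_match + res$n_mismatch + res$n_ins  # read bases aligned
  cols <- res$n_match + res$n_mismatch + res$n_ins + res$n_del
  identity <- ifelse(cols > 0, res$n_match / cols, 0)
  aligned_fraction <- aligned / read_len
  out <- data.frame(read_id = read_id, cost = res$cost,
                    ref_start = res$ref_start, ref_end = res$ref_end,
                    cigar = res$cigar, n_match = res$n_match,
                    n_mismatch = res$n_mismatch, n_ins = res$n_ins,
                    n_del = res$n_del, aligned_fraction = aligned_fraction,
                    identity = identity,
                    passed_filters = aligned_fraction >= params$length_fraction &
                      identity >= params$similarity_fraction,
                    seq = reads, stringsAsFactors = FALSE)
  class(out) <- c("amplicon_alignments", "data.frame")
  out
}

#' Align a single read
#'
#' Convenience wrapper around [align_reads()] for one read.
#'
#' @inheritParams align_reads
#' @param read A single read sequence.
#' @return A one-row `amplicon_alignments` data.frame.
#' @export
align_read <- function(read, ref, params = alignment_params()) {
  align_reads(read, ref, params)
}

#' Pile up passing alignments and apply variant filters
#'
#' Counts, at every reference position, the bases (and deletions) observed in
#' filter-passing alignments, then flags which (position, alternative)
#' observations are reportable under the variant filter. For paired data the
#' two mates of a fragment are counted once per covered position: where mates
#' overlap, mate 1's call wins. A fragment counts as indel-containing when any
#' passing mate's alignment contains an insertion or deletion operation.
#'
#' @param alignments An `amplicon_alignments` data.frame from [align_reads()].
#' @param ref The reference sequence the alignments were computed against.
#' @param filter A [variant_filter()].
#' @param fragment Integer vector assigning each alignment row to a fragment
#'   (default: each read its own fragment).
#' @param mate Integer vector (1 or 2) per alignment row; mate 1 takes
#'   precedence in overlaps.
#' @return An object of class `amplicon_pileup`: a list with `counts` (5 x L
#'   integer matrix, rows A/C/G/T/del), `coverage` (length-L), `ref_base`,
#'   `reported` (5 x L logical: passes all three gates and differs from the
#'   reference base), `n_fragments_passing`, `n_fragments_indel`, `filter`.
#' @export
pileup_and_filter <- function(alignments, ref, filter = variant_filter(),
                              fragment = NULL, mate = NULL) {
  ref <- toupper(ref)
  L <- nchar(ref)
  n <- nrow(alignments)
  if (is.null(fragment)) fragment <- seq_len(n)
  if (is.null(mate)) mate <- rep(1L, n)
  stopifnot(length(fragment) == n, length(mate) == n)
  if (!any(alignments$passed_filters))
    warning("no alignments pass the read filters; pileup is empty")
  ord <- order(fragment, mate)
  n_frag <- max(fragment)
  pres <- .pileup_cpp(L, as.integer(fragment[ord]), as.integer(mate[ord]),
                      alignments$seq[ord], as.integer(alignments$ref_start[ord]),
                      alignments$cigar[ord], alignments$passed_filters[ord],
                      as.integer(n_frag))
  counts <- pres$counts
  rownames(counts) <- c("A", "C", "G", "T", "del")
  coverage <- colSums(counts)
  ref_base <- strsplit(ref, "")[[1]]
  freq <- sweep(counts, 2, pmax(coverage, 1L), "/") * 100
  reported <- counts >= filter$min_count &
    freq >= filter$min_frequency_percent &
    matrix(coverage >= filter$min_coverage, 5, L, byrow = TRUE)
  # the reference base itself is not a variant
  for (b in c("A", "C", "G", "T")) reported[b, ref_base == b] <- FALSE
  structure(list(counts = counts, coverage = coverage, ref_base = ref_base,
                 frequency = freq, reported = reported,
                 n_fragments_passing = sum(pres$frag_pass),
                 n_fragments_indel = sum(pres$frag_indel & pres$frag_pass),
                 filter = filter),
            class = "amplicon_pileup")
}

#' @export
print.amplicon_pileup <- function(x, ...) {
  cat(sprintf("<amplicon_pileup> %d positions, %d passing fragments, %d with indels, %d reported variants\n",
              length(x$coverage), x$n_fragments_passing, x$n_fragments_indel,
              sum(x$reported)))
  invisible(x)
}
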