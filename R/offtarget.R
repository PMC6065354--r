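# Off-target candidate enumeration: exhaustive Hamming-distance scan of a
# spacer against subject sequences under canonical/non-canonical PAMs.

#' Scan subject sequences for candidate off-target sites
#'
#' Exhaustively enumerates protospacer-length sites immediately 5' of every
#' PAM occurrence on both strands of every subject and reports those within
#' `max_mismatches` Hamming mismatches of the spacer. No DNA/RNA bulges are
#' considered. When the true target locus is among the subjects it appears as
#' a 0-mismatch hit.
#'
#' @param spacer Protospacer sequence, 5'->3' on the PAM-bearing strand
#'   (18-20 nt typical).
#' @param subjects Named character vector of subject DNA sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param pam A [pam_spec()]; use `pam_spec(c("NGG", "NAG"))` to include the
#'   non-canonical PAM.
#' @param max_mismatches Maximum Hamming mismatches (default 4).
#' @return A data.frame with columns `subject_id`, `pam_start` (0-based index
#'   on the subject's sense strand of the leftmost PAM base), `strand`,
#'   `mismatch_count`, `mismatch_positions` (comma-separated PAM-relative
#'   positions), `min_mm_dist_to_pam` (distance of the PAM-proximal-most
#'   mismatch; NA for perfect hits), `pam_seq`, `site_seq`. Sorted by
#'   `mismatch_count`, then subject, strand and coordinate. Subjects shorter
#'   than the spacer are skipped with a message.
#' @export
scan_offtargets <- function(spacer, subjects, pam = pam_spec(),
                            max_mismatches = 4L) {
  spacer <- toupper(spacer)
  check_dna(spacer, allow_n = FALSE, what = "spacer")
  k <- nchar(spacer)
  if (k < 10L) stop("spacer is implausibly short", call. = FALSE)
  if (inherits(subjects, "DNAStringSet")) {
    subjects <- structure(as.character(subjects), names = names(subjects))
  }
  if (is.null(names(subjects)))
    names(subjects) <- paste0("subject", seq_along(subjects))
  spacer_chars <- strsplit(spacer, "")[[1]]
  rows <- list()
  for (sid in names(subjects)) {
    subj <- toupper(subjects[[sid]])
    if (nchar(subj) < k + pam$pam_len) {
      message("skipping subject ", sid, ": shorter than spacer + PAM")
      next
    }
    sites <- find_pam_sites(subj, pam, both_strands = TRUE)
    n <- nchar(subj)
    for (i in seq_len(nrow(sites))) {
      p <- sites$pam_start[i]
      strand <- sites$strand[i]
      site <- tryCatch(
        spacer_for(subj, p, strand, spacer_len = k, pam_len = pam$pam_len),
        error = function(e) NULL)
      if (is.null(site) || grepl("N", site)) next
      site_chars <- strsplit(site, "")[[1]]
      mm_rel <- seq(-k, -1L)[site_chars != spacer_chars]
      if (length(mm_rel) > max_mismatches) next
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid,
        pam_start = p,
        strand = strand,
        mismatch_count = length(mm_rel),
        mismatch_positions = paste(mm_rel, collapse = ","),
        min_mm_dist_to_pam = if (length(mm_rel)) min(abs(mm_rel)) else NA_integer_,
        pam_seq = sites$pam_seq[i],
        site_seq = site,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    subject_id = character(0), pam_start = integer(0), strand = character(0),
    mismatch_count = integer(0), mismatch_positions = character(0),
    min_mm_dist_to_pam = integer(0), pam_seq = character(0),
    site_seq = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$mismatch_count, out$subject_id,
                   out$strand == "antisense", out$pam_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank off-target hits by risk
#'
#' Orders hits by ascending mismatch count; among ties, sites whose mismatches
#' sit farther from the PAM rank first (PAM-proximal "seed" mismatches
#' suppress Cas9 activity, so such sites are lower-risk).
#'
#' @param hits Output of [scan_offtargets()].
#' @return The same data.frame, reordered, with a `rank` column prepended.
#' @export
rank_offtargets <- function(hits) {
  dist <- ifelse(is.na(hits$min_mm_dist_to_pam), Inf, hits$min_mm_dist_to_pam)
  ord <- order(hits$mismatch_count, -dist, hits$subject_id, hits$pam_start)
  out <- hits[ord, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Write off-target hits as BED intervals
#'
#' Emits the protospacer+PAM footprint of each hit as 0-based half-open BED.
#'
#' @param hits Output of [scan_offtargets()].
#' @param spacer_len Spacer length used in the scan.
#' @param file Output path.
#' @param pam_len PAM length (default 3).
#' @export
offtarget_bed <- function(hits, spacer_len, file, pam_len = 3L) {
  sense <- hits$strand == "sense"
  start <- ifelse(sense, hits$pam_start - spacer_len, hits$pam_start)
  end <- ifelse(sense, hits$pam_start + pam_len,
                hits$pam_start + pam_len + spacer_len)
  bed <- data.frame(chrom = hits$subject_id, start = start, end = end,
                    name = paste0("mm", hits$mismatch_count),
                    score = hits$mismatch_count,
                    strand = ifelse(sense, "+", "-"))
  write.table(bed, file, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
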