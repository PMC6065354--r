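# PAM-relative mutation spectrum: re-index a filtered pileup onto the
# -22..-1 axis, and the substitution:indel purity ratio.

#' Tabulate the PAM-relative mutation spectrum
#'
#' Re-indexes reference positions onto PAM-relative coordinates (-1 is the
#' base immediately 5' of the PAM) and reports, per position, the coverage and
#' percent frequency of each substitution class and deletion. Frequencies are
#' taken from variants passing the [variant_filter()] gates; sub-threshold
#' observations stay in the raw counts at zero reported frequency. The
#' per-read indel frequency is the percentage of passing fragments whose
#' alignment contains at least one insertion or deletion anywhere in the
#' amplicon.
#'
#' @param pileup An `amplicon_pileup` from [pileup_and_filter()].
#' @param pam_start 0-based reference index of the leftmost PAM base.
#' @param window Integer length-2 PAM-relative window (default `c(-22, -1)`).
#' @param locus_id Label carried into the output.
#' @return An object of class `mutation_spectrum`: list with `table` (one row
#'   per window position: `pam_relative_pos`, `ref_index`, `ref_base`,
#'   `coverage`, counts `n_A`..`n_del`, reported frequencies `f_A`..`f_del`
#'   in percent, 2 decimals), `indel_frequency_percent`, `n_reads_passing`,
#'   `pam_start`, `locus_id`.
#' @export
mutation_spectrum <- function(pileup, pam_start, window = c(-22L, -1L),
                              locus_id = "locus") {
  stopifnot(inherits(pileup, "amplicon_pileup"))
  window <- sort(as.integer(window))
  rels <- seq(window[1], window[2])
  idx <- pam_start + rels  # 0-based reference indices
  L <- length(pileup$coverage)
  if (any(idx < 0L | idx >= L))
    stop("window extends outside the amplicon", call. = FALSE)
  cols <- idx + 1L
  cnt <- pileup$counts[, cols, drop = FALSE]
  rep_freq <- ifelse(pileup$reported[, cols, drop = FALSE],
                     pileup$frequency[, cols, drop = FALSE], 0)
  tab <- data.frame(
    pam_relative_pos = rels,
    ref_index = idx,
    ref_base = pileup$ref_base[cols],
    coverage = as.integer(pileup$coverage[cols]),
    n_A = cnt["A", ], n_C = cnt["C", ], n_G = cnt["G", ], n_T = cnt["T", ],
    n_del = cnt["del", ],
    f_A = round(rep_freq["A", ], 2), f_C = round(rep_freq["C", ], 2),
    f_G = round(rep_freq["G", ], 2), f_T = round(rep_freq["T", ], 2),
    f_del = round(rep_freq["del", ], 2),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  indel_pct <- if (pileup$n_fragments_passing > 0)
    100 * pileup$n_fragments_indel / pileup$n_fragments_passing else 0
  structure(list(table = tab,
                 indel_frequency_percent = indel_pct,
                 n_reads_passing = pileup$n_fragments_passing,
                 pam_start = pam_start, locus_id = locus_id),
            class = "mutation_spectrum")
}

#' @export
print.mutation_spectrum <- function(x, ...) {
  cat(sprintf("<mutation_spectrum> %s: positions %d..%d, %d passing reads, indel %.2f%%\n",
              x$locus_id, min(x$table$pam_relative_pos),
              max(x$table$pam_relative_pos), x$n_reads_passing,
              x$indel_frequency_percent))
  nz <- x$table[x$table$f_A + x$table$f_C + x$table$f_G + x$table$f_T +
                  x$table$f_del > 0, ]
  if (nrow(nz)) {
    cat("reported variants:\n")
    print(nz[, c("pam_relative_pos", "ref_base", "coverage",
                 "f_A", "f_C", "f_G", "f_T", "f_del")], row.names = FALSE)
  } else cat("no reported variants in window\n")
  invisible(x)
}

#' Frequency of a specific substitution at a PAM-relative position
#'
#' @param spectrum A `mutation_spectrum`.
#' @param pos PAM-relative position (e.g. -19).
#' @param alt Alternative base ("A", "C", "G", "T") or "del".
#' @return Reported frequency in percent.
#' @export
spectrum_frequency <- function(spectrum, pos, alt = "T") {
  stopifnot(inherits(spectrum, "mutation_spectrum"))
  row <- match(as.integer(pos), spectrum$table$pam_relative_pos)
  if (is.na(row)) stop("position not in spectrum window", call. = FALSE)
  spectrum$table[[paste0("f_", alt)]][row]
}

#' Substitution:indel ratio
#'
#' The base-editing purity measure: the summed targeted C>T substitution
#' frequency divided by the indel frequency, reported to 2 decimals. Accepts
#' either a `mutation_spectrum` (with `target_positions` naming the targeted
#' PAM-relative cytosines) or plain percent frequencies.
#'
#' @param x A `mutation_spectrum`, or numeric substitution frequencies in
#'   percent (summed if several).
#' @param target_positions PAM-relative positions of the targeted cytosines
#'   (spectrum input only); their C>T (`f_T`) frequencies are summed.
#' @param indel_pct Indel frequency in percent (numeric input only).
#' @return A list with `ratio` (2 decimals; `Inf` with `zero_indel = TRUE`
#'   when the indel frequency is zero), `substitution_percent`,
#'   `indel_percent`, `zero_indel`.
#' @examples
#' substitution_indel_ratio(2.19, indel_pct = 0.91)$ratio  # 2.41
#' @export
substitution_indel_ratio <- function(x, target_positions = NULL,
                                     indel_pct = NULL) {
  if (inherits(x, "mutation_spectrum")) {
    if (is.null(target_positions))
      stop("target_positions required for a spectrum input", call. = FALSE)
    sub_pct <- sum(vapply(target_positions, function(p)
      spectrum_frequency(x, p, "T"), numeric(1)))
    indel_pct <- x$indel_frequency_percent
  } else {
    if (is.null(indel_pct))
      stop("indel_pct required for numeric input", call. = FALSE)
    sub_pct <- sum(x)
  }
  zero <- indel_pct == 0
  list(ratio = if (zero) Inf else round(sub_pct / indel_pct, 2),
       substitution_percent = sub_pct, indel_percent = indel_pct,
       zero_indel = zero)
}

#' Run the full amplicon spectrum pipeline
#'
#' Aligns reads (single or paired) to the reference amplicon, applies the
#' read and variant filters, and tabulates the PAM-relative mutation
#' spectrum.
#'
#' @param reads1 Character vector of reads (mate 1 for paired data).
#' @param ref Reference amplicon sequence.
#' @param pam_start 0-based reference index of the leftmost PAM base.
#' @param reads2 Optional mate-2 reads, parallel to `reads1`.
#' @param reads2_orientation `"reverse"` (FASTQ convention: mate 2 is the
#'   reverse complement of the fragment's 3' end and is flipped onto the
#'   sense strand before alignment) or `"forward"`.
#' @param params An [alignment_params()].
#' @param filter A [variant_filter()].
#' @param window PAM-relative window (default `c(-22, -1)`).
#' @param locus_id Label for the output.
#' @return A `mutation_spectrum`.
#' @export
amplicon_pipeline <- function(reads1, ref, pam_start, reads2 = NULL,
                              reads2_orientation = c("reverse", "forward"),
                              params = alignment_params(),
                              filter = variant_filter(),
                              window = c(-22L, -1L), locus_id = "locus") {
  reads2_orientation <- match.arg(reads2_orientation)
  n <- length(reads1)
  aln1 <- align_reads(reads1, ref, params,
                      read_id = paste0("frag", seq_len(n), "/1"))
  if (!is.null(reads2)) {
    stopifnot(length(reads2) == n)
    if (reads2_orientation == "reverse") reads2 <- revcomp(reads2)
    aln2 <- align_reads(reads2, ref, params,
                        read_id = paste0("frag", seq_len(n), "/2"))
    aln <- rbind(aln1, aln2)
    fragment <- c(seq_len(n), seq_len(n))
    mate <- rep(c(1L, 2L), each = n)
  } else {
    aln <- aln1
    fragment <- seq_len(n)
    mate <- rep(1L, n)
  }
  pu <- pileup_and_filter(aln, ref, filter, fragment = fragment, mate = mate)
  mutation_spectrum(pu, pam_start, window, locus_id)
}
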