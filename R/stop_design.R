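# Stop-codon edit design: scan coding sequences for cytosines whose C>T
# deamination within the PAM-relative editing window creates a premature stop
# codon, and emit scored sgRNA designs.

#' Construct a coding sequence record
#'
#' Bundles a genomic/coding DNA sequence with explicit CDS offsets. Intron and
#' exon structure is carried by the offsets rather than letter case, so
#' spacers may legally span intron/exon boundaries.
#'
#' @param id Locus identifier.
#' @param seq DNA string (A/C/G/T/N); uppercased on input.
#' @param cds_start 0-based offset of the first base of the start codon.
#' @param cds_end 0-based offset one past the last CDS base (half-open);
#'   `cds_end - cds_start` must be a positive multiple of 3.
#' @return An object of class `coding_sequence`.
#' @export
coding_sequence <- function(id, seq, cds_start = 0L, cds_end = nchar(seq)) {
  seq <- toupper(seq)
  check_dna(seq, allow_n = TRUE, what = "seq")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < 0L || cds_end > nchar(seq) || cds_end <= cds_start)
    stop("CDS offsets out of bounds", call. = FALSE)
  if ((cds_end - cds_start) %% 3L != 0L)
    stop("CDS length must be a positive multiple of 3", call. = FALSE)
  structure(list(id = as.character(id), seq = seq,
                 cds_start = cds_start, cds_end = cds_end),
            class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt, CDS [%d, %d) (%d codons)\n",
              x$id, nchar(x$seq), x$cds_start, x$cds_end,
              (x$cds_end - x$cds_start) %/% 3L))
  invisible(x)
}

#' PAM specification
#'
#' @param patterns Character vector of IUPAC PAM motifs; the canonical SpCas9
#'   motif is `"NGG"`, with `"NAG"` as the common non-canonical alternative.
#' @param pam_len PAM length; all patterns must have this length.
#' @return An object of class `pam_spec`.
#' @export
pam_spec <- function(patterns = "NGG", pam_len = 3L) {
  patterns <- toupper(patterns)
  if (!all(nchar(patterns) == pam_len))
    stop("every PAM pattern must have length pam_len", call. = FALSE)
  bad <- setdiff(unique(unlist(strsplit(patterns, ""))), names(IUPAC_SETS))
  if (length(bad))
    stop("non-IUPAC characters in PAM pattern: ", paste(bad, collapse = ","),
         call. = FALSE)
  structure(list(patterns = patterns, pam_len = as.integer(pam_len)),
            class = "pam_spec")
}

#' Position-wise deamination efficiency profile
#'
#' Percent deamination rate by PAM-relative position. The default profile is
#' the nCas9-PmCDA1 yeast estimate for the -20..-16 editing window: roughly
#' 5, 25, 45, 35 and 5 percent at positions -20, -19, -18, -17 and -16.
#' Positions outside the profile score 0.
#'
#' @param weights Named numeric vector: names are PAM-relative positions
#'   (negative integers, -1 = base immediately 5' of the PAM), values percent
#'   rates in \[0, 100\].
#' @return An object of class `efficiency_profile`.
#' @export
efficiency_profile <- function(weights = c(`-20` = 5, `-19` = 25, `-18` = 45,
                                           `-17` = 35, `-16` = 5)) {
  if (is.null(names(weights)) || anyNA(suppressWarnings(as.integer(names(weights)))))
    stop("weights must be named by integer PAM-relative positions", call. = FALSE)
  if (any(weights < 0 | weights > 100))
    stop("weights must lie in [0, 100]", call. = FALSE)
  structure(list(weights = weights), class = "efficiency_profile")
}

#' Score a PAM-relative position under an efficiency profile
#'
#' @param pos Integer vector of PAM-relative positions (e.g. -18).
#' @param profile An [efficiency_profile()].
#' @return Numeric vector of percent deamination rates; 0 outside the profile.
#' @examples
#' score_position(-18)  # 45 under the default profile
#' @export
score_position <- function(pos, profile = efficiency_profile()) {
  stopifnot(inherits(profile, "efficiency_profile"))
  w <- profile$weights[as.character(as.integer(pos))]
  w[is.na(w)] <- 0
  unname(w)
}

#' Find PAM sites in a sequence
#'
#' IUPAC-aware scan for PAM motifs on the sense strand and, optionally, the
#' antisense strand. Antisense matches are reported with coordinates of the
#' motif occurrence mapped back onto the given (sense) record: `pam_start` is
#' the 0-based sense-strand index of the leftmost base of the reverse
#' complement of the motif occurrence.
#'
#' @param seq DNA string.
#' @param pam A [pam_spec()].
#' @param both_strands Scan the antisense strand as well?
#' @return A data.frame with columns `pam_start` (0-based), `strand`
#'   ("sense"/"antisense") and `pam_seq` (motif occurrence, 5'->3' on its own
#'   strand), sorted by strand then position.
#' @export
find_pam_sites <- function(seq, pam = pam_spec(), both_strands = TRUE) {
  seq <- toupper(seq)
  check_dna(seq, allow_n = TRUE, what = "seq")
  stopifnot(inherits(pam, "pam_spec"))
  if (nchar(seq) == 0L) stop("seq must be non-empty", call. = FALSE)
  n <- nchar(seq)
  k <- pam$pam_len
  scan_one <- function(subject, strand_label) {
    chars <- strsplit(subject, "")[[1]]
    hits <- sort(unique(unlist(lapply(pam$patterns, iupac_find_all,
                                      subject_chars = chars))))
    if (!length(hits)) return(NULL)
    start_on_sense <- if (strand_label == "sense") hits else n - k - hits
    data.frame(pam_start = as.integer(start_on_sense),
               strand = strand_label,
               pam_seq = substring(subject, hits + 1L, hits + k),
               stringsAsFactors = FALSE)
  }
  out <- scan_one(seq, "sense")
  if (both_strands) out <- rbind(out, scan_one(revcomp(seq), "antisense"))
  if (is.null(out))
    return(data.frame(pam_start = integer(0), strand = character(0),
                      pam_seq = character(0), stringsAsFactors = FALSE))
  out <- out[order(out$strand == "antisense", out$pam_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the spacer (protospacer) for a PAM site
#'
#' Returns the `spacer_len` bases immediately 5' of the PAM on the PAM-bearing
#' strand, 5'->3'. With the default 18-nt spacer a target cytosine at -19 or
#' -20 lies outside the spacer itself; that is legal and common.
#'
#' @param record A [coding_sequence()] (or plain DNA string).
#' @param pam_start 0-based sense-strand index of the PAM (as reported by
#'   [find_pam_sites()]).
#' @param strand "sense" or "antisense".
#' @param spacer_len Spacer length (default 18).
#' @param pam_len PAM length (default 3), needed for antisense arithmetic.
#' @return DNA string of length `spacer_len`.
#' @export
spacer_for <- function(record, pam_start, strand = c("sense", "antisense"),
                       spacer_len = 18L, pam_len = 3L) {
  strand <- match.arg(strand)
  seq <- if (inherits(record, "coding_sequence")) record$seq else toupper(record)
  n <- nchar(seq)
  if (strand == "sense") {
    from <- pam_start - spacer_len  # 0-based
    if (from < 0L || pam_start + pam_len > n)
      stop("spacer runs off the record", call. = FALSE)
    substring(seq, from + 1L, pam_start)
  } else {
    # PAM occupies sense [pam_start, pam_start + pam_len); the spacer is 3'
    # of it on the sense strand, read as reverse complement.
    from <- pam_start + pam_len      # 0-based first sense base of spacer span
    to <- from + spacer_len - 1L
    if (pam_start < 0L || to >= n)
      stop("spacer runs off the record", call. = FALSE)
    revcomp(substring(seq, from + 1L, to + 1L))
  }
}

#' Enumerate candidate stop-codon-introducing edits
#'
#' Scans a coding sequence for cytosines located in the editing window
#' (default -20..-16) relative to a PAM on the same strand, whose C>T
#' deamination converts a codon into a stop codon (TAA, TAG or TGA).
#' Sense-strand candidates are direct C>T edits; antisense candidates are
#' cytosines on the reverse complement, i.e. G>A changes on the coding strand
#' (only Trp TGG codons can yield a stop this way). Every (cytosine, PAM) pair
#' is reported independently: a cytosine editable from two overlapping PAMs
#' yields two candidates with their own scores. Bystander cytosines in the
#' window are listed, never filtered. Windows or codons containing N are
#' skipped; the number skipped is available as `attr(x, "n_skipped_N")`.
#'
#' @param cds A [coding_sequence()].
#' @param pam A [pam_spec()].
#' @param profile An [efficiency_profile()]; a candidate's score is the
#'   profile weight at its PAM-relative position.
#' @param window Integer length-2 vector, PAM-relative editing window
#'   (default `c(-20, -16)`).
#' @param spacer_len Spacer length (default 18); candidates whose spacer would
#'   run off the record are skipped.
#' @param sense_only Restrict to sense-strand (direct C>T) candidates.
#' @return A data.frame of candidates, one row per (cytosine, PAM) pair, with
#'   columns `locus_id`, `c_pos_in_record` (0-based), `cds_c_number` (1-based
#'   "c." coordinate of the edited coding base), `pam_relative_pos`, `strand`,
#'   `codon_before`, `codon_after`, `codon_index` (1-based codon number),
#'   `spacer_seq`, `pam_seq`, `score`, `other_window_cytosines`
#'   (comma-separated PAM-relative positions). Sorted by `cds_c_number`, then
#'   score descending.
#' @export
enumerate_stop_edits <- function(cds, pam = pam_spec(),
                                 profile = efficiency_profile(),
                                 window = c(-20L, -16L), spacer_len = 18L,
                                 sense_only = FALSE) {
  stopifnot(inherits(cds, "coding_sequence"))
  window <- sort(as.integer(window))
  rels <- seq(window[1], window[2])
  seq <- cds$seq
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  sites <- find_pam_sites(seq, pam, both_strands = !sense_only)
  n_skipped <- 0L
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    p <- sites$pam_start[i]
    strand <- sites$strand[i]
    # index on the sense strand of the base at PAM-relative position r on the
    # PAM-bearing strand
    sense_idx <- function(r) {
      if (strand == "sense") p + r else p + pam_spec_len(pam) - 1L - r
    }
    win_idx <- vapply(rels, sense_idx, integer(1))
    in_rec <- win_idx >= 0L & win_idx < n  # window may overhang the record
    if (!any(in_rec)) next
    win_bases_sense <- chars[win_idx[in_rec] + 1L]
    if (any(win_bases_sense == "N")) { n_skipped <- n_skipped + 1L; next }
    # base on the PAM-bearing strand at each window position
    win_bases <- if (strand == "sense") win_bases_sense else
      chartr("ACGT", "TGCA", win_bases_sense)
    c_rels <- rels[in_rec][win_bases == "C"]
    if (!length(c_rels)) next
    spc <- tryCatch(spacer_for(seq, p, strand, spacer_len,
                               pam_len = pam$pam_len),
                    error = function(e) NULL)
    if (is.null(spc)) next
    for (r in c_rels) {
      si <- sense_idx(r)
      if (si < cds$cds_start || si >= cds$cds_end) next
      cds_num <- si - cds$cds_start + 1L
      codon_idx0 <- (si - cds$cds_start) %/% 3L
      cstart <- cds$cds_start + 3L * codon_idx0
      if (cstart + 3L > cds$cds_end) next
      codon_before <- substring(seq, cstart + 1L, cstart + 3L)
      if (grepl("N", codon_before)) { n_skipped <- n_skipped + 1L; next }
      edited_base <- if (strand == "sense") "T" else "A"  # C>T, or G>A on sense
      codon_after <- codon_before
      substr(codon_after, si - cstart + 1L, si - cstart + 1L) <- edited_base
      if (!(codon_after %in% STOP_CODONS)) next
      if (codon_before %in% STOP_CODONS) next  # already a stop; nothing created
      rows[[length(rows) + 1L]] <- data.frame(
        locus_id = cds$id,
        c_pos_in_record = si,
        cds_c_number = cds_num,
        pam_relative_pos = r,
        strand = strand,
        codon_before = codon_before,
        codon_after = codon_after,
        codon_index = codon_idx0 + 1L,
        spacer_seq = spc,
        pam_seq = sites$pam_seq[i],
        score = score_position(r, profile),
        other_window_cytosines = paste(setdiff(c_rels, r), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    locus_id = character(0), c_pos_in_record = integer(0),
    cds_c_number = integer(0), pam_relative_pos = integer(0),
    strand = character(0), codon_before = character(0),
    codon_after = character(0), codon_index = integer(0),
    spacer_seq = character(0), pam_seq = character(0), score = numeric(0),
    other_window_cytosines = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$cds_c_number, -out$score), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped_N") <- n_skipped
  out
}

pam_spec_len <- function(pam) pam$pam_len

#' Read coding sequence records from FASTA plus a locus table
#'
#' @param fasta Path to a FASTA file of locus sequences.
#' @param loci Path to a tab-separated table with columns `id`, `cds_start`,
#'   `cds_end` (0-based, half-open).
#' @return A named list of [coding_sequence()] objects.
#' @export
read_coding_sequences <- function(fasta, loci) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  tab <- read.delim(loci, stringsAsFactors = FALSE)
  need <- c("id", "cds_start", "cds_end")
  if (!all(need %in% names(tab)))
    stop("locus table must have columns id, cds_start, cds_end", call. = FALSE)
  ids <- sub("\\s.*$", "", names(seqs))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    j <- match(tab$id[i], ids)
    if (is.na(j)) stop("locus ", tab$id[i], " not found in FASTA", call. = FALSE)
    coding_sequence(tab$id[i], as.character(seqs[[j]]),
                    tab$cds_start[i], tab$cds_end[i])
  })
  names(out) <- tab$id
  out
}
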