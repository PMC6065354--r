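# Independent oracle implementations used to cross-check the package. These
# deliberately share no code with the package internals: plain-R string
# handling, naive quadratic scans, full dynamic programming without the fast
# path.

o_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

o_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Every 0-based position/strand where one of the IUPAC patterns matches,
# testing every position of every strand one base at a time.
o_pam_scan <- function(seq, patterns, both_strands = TRUE) {
  scan1 <- function(s, strand) {
    sc <- strsplit(s, "")[[1]]
    out <- NULL
    for (pat in patterns) {
      pc <- strsplit(pat, "")[[1]]
      k <- length(pc)
      if (length(sc) < k) next
      for (i in 0:(length(sc) - k)) {
        ok <- TRUE
        for (j in seq_len(k)) {
          if (!(sc[i + j] %in% o_iupac[[pc[j]]])) { ok <- FALSE; break }
        }
        if (ok) out <- rbind(out, data.frame(pos = i, strand = strand))
      }
    }
    out
  }
  res <- scan1(seq, "sense")
  if (both_strands) {
    rc <- scan1(o_revcomp(seq), "antisense")
    if (!is.null(rc)) {
      # map revcomp coordinates back to the sense record
      k <- nchar(seq)
      # pattern length is uniform (PAM), take from patterns[1]
      plen <- nchar(patterns[1])
      rc$pos <- k - plen - rc$pos
      res <- rbind(res, rc)
    }
  }
  if (is.null(res)) res <- data.frame(pos = integer(0), strand = character(0))
  unique(res[order(res$strand, res$pos), ])
}

# Full-matrix semi-global alignment cost (read global, ref ends free),
# no traceback, no shortcuts.
o_align_cost <- function(read, ref, mm = 2, ins = 3, del = 3) {
  n <- nchar(read); m <- nchar(ref)
  rc <- strsplit(read, "")[[1]]; fc <- strsplit(ref, "")[[1]]
  prev <- rep(0, m + 1)
  for (i in 1:n) {
    cur <- numeric(m + 1)
    cur[1] <- i * ins
    for (j in 1:m) {
      cur[j + 1] <- min(prev[j] + if (rc[i] == fc[j]) 0 else mm,
                        prev[j + 1] + ins,
                        cur[j] + del)
    }
    prev <- cur
  }
  min(prev)
}

# Naive stop-edit enumeration: every C on either strand x every PAM x window
# membership x genetic-code check, with no shared machinery.
o_stop_codons <- c("TAA", "TAG", "TGA")
o_enumerate <- function(seq, cds_start, cds_end, window = c(-20, -16),
                        spacer_len = 18, patterns = "NGG", sense_only = FALSE) {
  n <- nchar(seq)
  sc <- strsplit(seq, "")[[1]]
  plen <- nchar(patterns[1])
  pams <- o_pam_scan(seq, patterns, both_strands = !sense_only)
  out <- NULL
  for (r in seq_len(nrow(pams))) {
    p <- pams$pos[r]; strand <- pams$strand[r]
    for (rel in window[1]:window[2]) {
      si <- if (strand == "sense") p + rel else p + plen - 1 - rel
      if (si < 0 || si >= n) next
      base_on_pam_strand <- if (strand == "sense") sc[si + 1] else
        chartr("ACGT", "TGCA", sc[si + 1])
      if (base_on_pam_strand != "C") next
      # spacer in bounds?
      if (strand == "sense") { if (p - spacer_len < 0) next }
      else { if (p + plen + spacer_len > n) next }
      if (si < cds_start || si >= cds_end) next
      codon0 <- (si - cds_start) %/% 3
      cst <- cds_start + 3 * codon0
      if (cst + 3 > cds_end) next
      before <- paste(sc[(cst + 1):(cst + 3)], collapse = "")
      if (grepl("N", before)) next
      after_chars <- sc[(cst + 1):(cst + 3)]
      after_chars[si - cst + 1] <- if (strand == "sense") "T" else "A"
      after <- paste(after_chars, collapse = "")
      if (!(after %in% o_stop_codons) || before %in% o_stop_codons) next
      out <- rbind(out, data.frame(c_pos = si, rel = rel, strand = strand,
                                   before = before, after = after,
                                   pam = p, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) out <- data.frame(c_pos = integer(0), rel = integer(0),
                                      strand = character(0),
                                      before = character(0),
                                      after = character(0), pam = integer(0))
  out[order(out$c_pos, out$rel, out$strand, out$pam), ]
}

# Naive off-target scan: position-by-position comparison at every PAM on
# either strand.
o_offtarget <- function(spacer, subject, patterns = "NGG", max_mm = 4) {
  k <- nchar(spacer)
  spc <- strsplit(spacer, "")[[1]]
  n <- nchar(subject)
  plen <- nchar(patterns[1])
  pams <- o_pam_scan(subject, patterns, both_strands = TRUE)
  out <- NULL
  for (r in seq_len(nrow(pams))) {
    p <- pams$pos[r]; strand <- pams$strand[r]
    if (strand == "sense") {
      if (p - k < 0) next
      site <- substring(subject, p - k + 1, p)
    } else {
      if (p + plen + k > n) next
      site <- o_revcomp(substring(subject, p + plen + 1, p + plen + k))
    }
    if (grepl("N", site)) next
    mm <- sum(strsplit(site, "")[[1]] != spc)
    if (mm <= max_mm)
      out <- rbind(out, data.frame(pam_start = p, strand = strand, mm = mm,
                                   stringsAsFactors = FALSE))
  }
  if (is.null(out)) out <- data.frame(pam_start = integer(0),
                                      strand = character(0), mm = integer(0))
  out[order(out$mm, out$strand, out$pam_start), ]
}

# Independent variant-filter gate: apply the three thresholds one by one.
o_filter_reported <- function(count, coverage, ref_is_alt, min_cov, min_count,
                              min_freq_pct) {
  if (ref_is_alt) return(FALSE)
  if (coverage < min_cov) return(FALSE)
  if (count < min_count) return(FALSE)
  if (coverage == 0) return(FALSE)
  100 * count / coverage >= min_freq_pct
}

random_dna <- function(n, with_n = FALSE) {
  alpha <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}
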