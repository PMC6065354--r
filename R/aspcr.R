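# Allele-specific PCR (ARMS) primer design for genotyping a single-nucleotide
# edit: the allele-specific primer's 3' terminus sits on the variant base and
# one additional destabilizing mismatch is engineered two bases from the 3'
# end, with an internal-control amplicon 800-1400 bp downstream.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

is_purine <- function(b) b %in% c("A", "G")

# Primer base vs template base mismatch class, worst (most destabilizing)
# first: purine-purine > pyrimidine-pyrimidine > wobble-ish purine/pyrimidine.
mismatch_class <- function(primer_base, template_base) {
  if (primer_base == unname(COMPLEMENT[template_base])) return(0L) # a match
  pu_p <- is_purine(primer_base); pu_t <- is_purine(template_base)
  if (pu_p && pu_t) 3L else if (!pu_p && !pu_t) 2L else 1L
}

# Choose the engineered-mismatch base for a primer position whose reference
# (sense-strand, primer-strand) base is `ref_here`, annealing to template base
# complement(ref_here). Prefer T when it mismatches; otherwise the most
# destabilizing alternative.
engineered_base <- function(ref_here) {
  template <- unname(COMPLEMENT[ref_here])
  if (mismatch_class("T", template) > 0L) return("T")
  cand <- setdiff(c("A", "C", "G", "T"), ref_here)
  cls <- vapply(cand, mismatch_class, integer(1), template_base = template)
  cand[which.max(cls)]
}

#' Melting temperature by the Wallace rule
#'
#' 2 degrees C per A/T base and 4 degrees C per G/C base.
#'
#' @param primer Primer sequence(s).
#' @return Numeric Tm in degrees C.
#' @export
primer_tm <- function(primer) {
  vapply(toupper(primer), function(p) {
    b <- strsplit(p, "")[[1]]
    2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C"))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Design allele-specific PCR primers for a single-nucleotide variant
#'
#' Builds a wild-type and a mutant allele-specific primer whose 3'-terminal
#' base sits on the variant (so only the matched allele extends), engineers
#' one additional destabilizing mismatch two bases from the 3' end of both
#' (preferring a T residue), places a shared primer to give a product near
#' `product_len_target`, and adds an internal-control pair amplifying a
#' region 800-1400 bp downstream of the variant.
#'
#' @param ref Reference (wild-type) sequence containing the variant and the
#'   downstream control region.
#' @param snv List or vector `(index, ref_base, alt_base)`: 0-based position
#'   of the variant, its reference base and its edited base.
#' @param primer_len Allele-specific primer length (default 20).
#' @param orientation `"forward"`: the allele-specific primers are forward
#'   primers ending 3' on the variant (wild ends in `ref_base`); `"reverse"`:
#'   they are reverse primers, so the wild primer ends in the complement of
#'   `ref_base` (a C>T edit gives wild G / mutant A, mirroring a reverse-
#'   primer design).
#' @param product_len_target Desired allele-specific product length
#'   (default 200).
#' @param control_offset Distance in bases from the variant to the start of
#'   the internal-control amplicon, within \[800, 1400\] (default 800).
#' @param control_len Internal-control product length (default 500).
#' @param control Include the internal-control pair? Disable for short
#'   references.
#' @return An object of class `aspcr_primer_set`: list with `snv`,
#'   `orientation`, `wild_primer`, `mut_primer`, `shared_primer`,
#'   `engineered_mismatch_offset` (2), `engineered_mismatch_base`,
#'   `product_len`, `wild_tm`, `mut_tm`, and (when `control`) `control_fwd`,
#'   `control_rev`, `control_product_len`, `control_start`.
#' @export
design_as_primers <- function(ref, snv, primer_len = 20L,
                              orientation = c("forward", "reverse"),
                              product_len_target = 200L,
                              control_offset = 800L, control_len = 500L,
                              control = TRUE) {
  orientation <- match.arg(orientation)
  ref <- toupper(ref)
  check_dna(ref, allow_n = FALSE, what = "ref")
  if (is.list(snv)) snv <- unlist(snv)
  idx <- as.integer(snv[1])
  ref_base <- toupper(snv[2]); alt_base <- toupper(snv[3])
  n <- nchar(ref)
  if (idx < 0L || idx >= n) stop("snv index out of bounds", call. = FALSE)
  if (substring(ref, idx + 1L, idx + 1L) != ref_base)
    stop("snv ref_base does not match the reference at that index",
         call. = FALSE)
  chars <- strsplit(ref, "")[[1]]

  if (orientation == "forward") {
    from <- idx - primer_len + 1L  # 0-based primer span [from, idx]
    if (from < 0L) stop("variant too close to the 5' end for primer_len",
                        call. = FALSE)
    prim <- chars[(from + 1L):(idx + 1L)]
    mm_i <- primer_len - 2L  # offset 2 from the 3' end (0 = terminal)
    eng <- engineered_base(prim[mm_i])
    prim[mm_i] <- eng
    wild <- prim; mut <- prim
    mut[primer_len] <- alt_base
    # shared reverse primer: product spans [from, rev_end]
    rev_end <- from + product_len_target - 1L
    if (rev_end >= n) stop("product_len_target runs off the reference",
                           call. = FALSE)
    shared <- revcomp(substring(ref, rev_end - primer_len + 2L, rev_end + 1L))
    product_len <- product_len_target
  } else {
    to <- idx + primer_len - 1L  # sense span [idx, to]; primer is its revcomp
    if (to >= n) stop("variant too close to the 3' end for primer_len",
                      call. = FALSE)
    prim <- rev(unname(COMPLEMENT[chars[(idx + 1L):(to + 1L)]]))
    mm_i <- primer_len - 2L
    eng <- engineered_base_revstrand(chars[idx + 3L])
    prim[mm_i] <- eng
    wild <- prim; mut <- prim
    mut[primer_len] <- unname(COMPLEMENT[alt_base])
    # shared forward primer: product spans [fwd_start, to]
    fwd_start <- to - product_len_target + 1L
    if (fwd_start < 0L) stop("product_len_target runs off the reference",
                             call. = FALSE)
    shared <- substring(ref, fwd_start + 1L, fwd_start + primer_len)
    product_len <- product_len_target
  }
  wild <- paste(wild, collapse = ""); mut <- paste(mut, collapse = "")

  out <- list(snv = list(index = idx, ref_base = ref_base, alt_base = alt_base),
              orientation = orientation,
              wild_primer = wild, mut_primer = mut, shared_primer = shared,
              engineered_mismatch_offset = 2L, engineered_mismatch_base = eng,
              product_len = product_len,
              wild_tm = primer_tm(wild), mut_tm = primer_tm(mut))
  if (abs(out$wild_tm - out$mut_tm) > 2)
    warning("allele primer Tm difference exceeds 2 degrees C")
  if (control) {
    if (control_offset < 800L || control_offset > 1400L)
      stop("control_offset must lie in [800, 1400]", call. = FALSE)
    cstart <- idx + control_offset
    cend <- cstart + control_len - 1L
    if (cend >= n)
      stop("reference too short for the internal-control amplicon; set control = FALSE",
           call. = FALSE)
    out$control_fwd <- substring(ref, cstart + 1L, cstart + primer_len)
    out$control_rev <- revcomp(substring(ref, cend - primer_len + 2L, cend + 1L))
    out$control_product_len <- control_len
    out$control_start <- cstart
  }
  class(out) <- "aspcr_primer_set"
  out
}

# Engineered base for a reverse-orientation primer position annealing to the
# sense-strand template base `sense_base`. The primer base occupying that
# position in the unmodified design is complement(sense_base); prefer T.
engineered_base_revstrand <- function(sense_base) {
  if (mismatch_class("T", sense_base) > 0L) return("T")
  cand <- setdiff(c("A", "C", "G", "T"), unname(COMPLEMENT[sense_base]))
  cls <- vapply(cand, mismatch_class, integer(1), template_base = sense_base)
  cand[which.max(cls)]
}

#' @export
print.aspcr_primer_set <- function(x, ...) {
  cat(sprintf("<aspcr_primer_set> %s>%s at index %d (%s orientation)\n",
              x$snv$ref_base, x$snv$alt_base, x$snv$index, x$orientation))
  cat(sprintf("  wild:   5'-%s-3' (Tm %.0fC)\n", x$wild_primer, x$wild_tm))
  cat(sprintf("  mutant: 5'-%s-3' (Tm %.0fC)\n", x$mut_primer, x$mut_tm))
  cat(sprintf("  shared: 5'-%s-3', product %d bp\n", x$shared_primer,
              x$product_len))
  if (!is.null(x$control_fwd))
    cat(sprintf("  control: %d bp starting %d bp downstream of the variant\n",
                x$control_product_len, x$control_start - x$snv$index))
  invisible(x)
}

#' In-silico PCR
#'
#' Finds all binding sites of a convergent primer pair on a template,
#' allowing internal mismatches but requiring an exact 3'-terminal match
#' (`max_3prime_mismatches = 0`), and returns the product lengths.
#'
#' @param ref Template sequence.
#' @param fwd Forward primer (anneals to the antisense strand; extends
#'   rightward on `ref`).
#' @param rev Reverse primer (anneals to the sense strand; extends leftward).
#' @param max_internal_mismatches Internal mismatches tolerated per primer
#'   (default 2; the engineered ARMS mismatch consumes one).
#' @param max_3prime_mismatches Mismatches tolerated at the 3'-terminal base
#'   (default 0 — the ARMS discrimination rule).
#' @param max_product Size cap on reported products (default 5000).
#' @return Integer vector of product lengths (empty when no product forms).
#' @export
in_silico_pcr <- function(ref, fwd, rev, max_internal_mismatches = 2L,
                          max_3prime_mismatches = 0L, max_product = 5000L) {
  ref <- toupper(ref); fwd <- toupper(fwd); rev <- toupper(rev)
  if (nchar(fwd) < 15L || nchar(rev) < 15L)
    stop("primers must be at least 15 nt", call. = FALSE)
  chars <- strsplit(ref, "")[[1]]
  bind_sites <- function(primer, three_prime_at_start) {
    pc <- strsplit(primer, "")[[1]]
    k <- length(pc)
    n <- length(chars)
    hits <- integer(0)
    if (n < k) return(hits)
    for (s in 0:(n - k)) {
      win <- chars[(s + 1L):(s + k)]
      mism <- win != pc
      term_i <- if (three_prime_at_start) 1L else k
      if (sum(mism[term_i]) > max_3prime_mismatches) next
      if (sum(mism[-term_i]) > max_internal_mismatches) next
      hits <- c(hits, s)
    }
    hits
  }
  fwd_sites <- bind_sites(fwd, three_prime_at_start = FALSE)
  # the reverse primer matches the sense strand as its reverse complement,
  # with its 3' terminus at the leftmost base of the occurrence
  rev_sites <- bind_sites(revcomp(rev), three_prime_at_start = TRUE)
  lr <- nchar(rev)
  lf <- nchar(fwd)
  products <- integer(0)
  for (f in fwd_sites) {
    for (r in rev_sites) {
      if (r < f + lf) next  # primers must not overlap / must be convergent
      len <- (r + lr) - f
      if (len <= max_product) products <- c(products, len)
    }
  }
  sort(products)
}

#' Verify that a primer set discriminates alleles
#'
#' Runs [in_silico_pcr()] for the wild and mutant primer pairs against both
#' the wild-type and the edited template.
#'
#' @param design An `aspcr_primer_set` from [design_as_primers()].
#' @param ref Wild-type template.
#' @return A data.frame with one row per (primer set, template) combination
#'   and a logical `amplifies` column.
#' @export
verify_as_primers <- function(design, ref) {
  ref <- toupper(ref)
  idx <- design$snv$index
  mut_ref <- ref
  substr(mut_ref, idx + 1L, idx + 1L) <- design$snv$alt_base
  combos <- expand.grid(allele_primer = c("wild", "mut"),
                        template = c("wild", "mut"),
                        stringsAsFactors = FALSE)
  combos$amplifies <- vapply(seq_len(nrow(combos)), function(i) {
    prim <- if (combos$allele_primer[i] == "wild") design$wild_primer
            else design$mut_primer
    tmpl <- if (combos$template[i] == "wild") ref else mut_ref
    prods <- if (design$orientation == "forward")
      in_silico_pcr(tmpl, prim, design$shared_primer)
    else
      in_silico_pcr(tmpl, design$shared_primer, prim)
    length(prods) > 0
  }, logical(1))
  combos
}
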