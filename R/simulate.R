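# Synthetic data generation: amplicon read sets with configured substitution,
# indel and sequencing-error rates, and founder -> F1 -> F2 cross tables under
# mosaicism and Mendelian segregation. Every simulation is deterministic for a
# fixed seed.

#' Read-simulation configuration
#'
#' Describes an amplicon read simulation emulating paired-end deep sequencing
#' of an edited locus: position-specific true edits applied per molecule,
#' rare indels, and uniform sequencing error on top.
#'
#' @param ref Reference amplicon sequence (the simulated fragments span it).
#' @param pam_start 0-based reference index of the leftmost PAM base.
#' @param sub_rates Data.frame with columns `pos` (PAM-relative), `alt`
#'   (base) and `rate` (per-molecule probability), or NULL for none. Rates at
#'   one position must sum to at most 1 (edits are mutually exclusive per
#'   molecule).
#' @param indel_rate Per-molecule probability of one indel (default 0).
#' @param indel_window Integer length-2 PAM-relative range in which indels are
#'   placed uniformly; the default, `c(-25, 4)`, is the protospacer extended
#'   by 5 bases on each side.
#' @param indel_geom_prob Success probability of the geometric tail of the
#'   indel length distribution; lengths are `1 + rgeom(indel_geom_prob)`
#'   (default 0.7, i.e. mostly single-base).
#' @param seq_error_rate Per-base uniform sequencing error (default 0.001).
#' @param fragment_len Fragment length; fragments are positioned uniformly on
#'   the reference. The default, NULL, uses the full reference — the PCR
#'   amplicon model, where every sequenced fragment is the amplicon.
#' @param read_len Read length (default 151).
#' @param paired Paired-end? Mate 1 reads the fragment 5' end on the sense
#'   strand; mate 2 reads the 3' end as reverse complement (default TRUE).
#' @param n_reads Number of fragments (read pairs when paired).
#' @param seed Integer seed; recorded in the FASTQ headers.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(ref, pam_start, sub_rates = NULL, indel_rate = 0,
                            indel_window = c(-25L, 4L), indel_geom_prob = 0.7,
                            seq_error_rate = 0.001, fragment_len = NULL,
                            read_len = 151L, paired = TRUE, n_reads,
                            seed = 1L) {
  ref <- toupper(ref)
  check_dna(ref, allow_n = FALSE, what = "ref")
  if (read_len > nchar(ref))
    stop("read_len exceeds the reference length", call. = FALSE)
  if (!is.null(fragment_len)) {
    fragment_len <- as.integer(fragment_len)
    if (fragment_len < read_len || fragment_len > nchar(ref))
      stop("fragment_len must lie in [read_len, nchar(ref)]", call. = FALSE)
  }
  if (!is.null(sub_rates)) {
    stopifnot(all(c("pos", "alt", "rate") %in% names(sub_rates)))
    if (any(sub_rates$rate < 0 | sub_rates$rate > 1))
      stop("substitution rates must lie in [0, 1]", call. = FALSE)
    per_pos <- tapply(sub_rates$rate, sub_rates$pos, sum)
    if (any(per_pos > 1))
      stop("substitution rates at one position sum to more than 1",
           call. = FALSE)
  }
  if (indel_rate < 0 || indel_rate > 1 || seq_error_rate < 0 ||
      seq_error_rate > 1)
    stop("rates must lie in [0, 1]", call. = FALSE)
  structure(list(ref = ref, pam_start = as.integer(pam_start),
                 sub_rates = sub_rates, indel_rate = indel_rate,
                 indel_window = sort(as.integer(indel_window)),
                 indel_geom_prob = indel_geom_prob,
                 seq_error_rate = seq_error_rate,
                 fragment_len = fragment_len,
                 read_len = as.integer(read_len), paired = isTRUE(paired),
                 n_reads = as.integer(n_reads), seed = as.integer(seed)),
            class = "read_sim_config")
}

# Mutate one base to a uniformly chosen different base (one RNG draw).
other_base <- function(b) {
  alts <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG", N = "ACGT")
  s <- alts[[b]]
  k <- sample.int(nchar(s), 1L)
  substring(s, k, k)
}

#' Simulate amplicon reads
#'
#' Draws `n_reads` molecules of the reference amplicon, applies configured
#' true edits per molecule (mutually exclusive per position), places indels,
#' cuts single or paired reads, and overlays uniform sequencing error.
#' Deterministic for a fixed seed. A truth table of per-molecule edits is
#' returned alongside the reads.
#'
#' @param cfg A [read_sim_config()].
#' @return A list with `reads1`, `reads2` (NULL when unpaired; mate 2 is the
#'   reverse complement of the fragment 3' end), `truth` (data.frame: one row
#'   per molecule with `frag_start`, logical columns per configured edit,
#'   `indel`, `indel_type`, `indel_len`, `indel_ref_index`; an edit or indel
#'   is recorded only when the fragment covers its site), and `cfg`.
#' @export
simulate_reads <- function(cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_reads
  ref <- cfg$ref
  L <- nchar(ref)
  flen <- if (is.null(cfg$fragment_len)) L else cfg$fragment_len
  frag_start <- if (flen == L) rep.int(0L, n) else
    sample.int(L - flen + 1L, n, replace = TRUE) - 1L
  mol <- if (flen == L) rep.int(ref, n) else
    substring(ref, frag_start + 1L, frag_start + flen)
  truth <- data.frame(molecule = seq_len(n), frag_start = frag_start)

  # true substitutions, mutually exclusive per position per molecule; an edit
  # exists on a molecule only when the fragment covers its position
  if (!is.null(cfg$sub_rates)) {
    for (p in unique(cfg$sub_rates$pos)) {
      block <- cfg$sub_rates[cfg$sub_rates$pos == p, , drop = FALSE]
      u <- runif(n)
      cum <- 0
      idx0 <- cfg$pam_start + as.integer(p)  # 0-based ref index
      if (idx0 < 0L || idx0 >= L)
        stop("substitution position outside the reference", call. = FALSE)
      covered <- idx0 >= frag_start & idx0 < frag_start + flen
      for (j in seq_len(nrow(block))) {
        sel <- u >= cum & u < cum + block$rate[j] & covered
        cum <- cum + block$rate[j]
        if (any(sel)) {
          if (flen == L) {
            substr(mol[sel], idx0 + 1L, idx0 + 1L) <- block$alt[j]
          } else {
            for (m in which(sel)) {
              loc <- idx0 - frag_start[m]
              substr(mol[m], loc + 1L, loc + 1L) <- block$alt[j]
            }
          }
        }
        truth[[sprintf("sub_%d_%s", as.integer(p), block$alt[j])]] <- sel
      }
    }
  }

  # indels: one per selected molecule, uniform position in the indel window
  truth$indel <- runif(n) < cfg$indel_rate
  truth$indel_type <- NA_character_
  truth$indel_len <- NA_integer_
  truth$indel_ref_index <- NA_integer_
  if (any(truth$indel)) {
    which_ind <- which(truth$indel)
    win <- cfg$pam_start + seq(cfg$indel_window[1], cfg$indel_window[2])
    win <- win[win >= 0L & win < L]
    pos <- sample(win, length(which_ind), replace = TRUE)
    type <- sample(c("ins", "del"), length(which_ind), replace = TRUE)
    len <- 1L + rgeom(length(which_ind), cfg$indel_geom_prob)
    ins_bases <- vapply(len, function(k)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    for (i in seq_along(which_ind)) {
      m <- which_ind[i]
      p0 <- pos[i] - frag_start[m]  # 0-based, fragment-local
      if (p0 < 0L || p0 >= flen) {  # fragment does not cover the indel site
        truth$indel[m] <- FALSE
        next
      }
      s <- mol[m]
      if (type[i] == "ins") {
        mol[m] <- paste0(substring(s, 1L, p0 + 1L), ins_bases[i],
                         substring(s, p0 + 2L, nchar(s)))
      } else {
        to <- min(p0 + len[i], nchar(s))
        mol[m] <- paste0(substring(s, 1L, p0), substring(s, to + 1L, nchar(s)))
      }
      truth$indel_type[m] <- type[i]
      truth$indel_len[m] <- len[i]
      truth$indel_ref_index[m] <- pos[i]
    }
  }

  # cut reads
  mlen <- nchar(mol)
  reads1 <- substring(mol, 1L, pmin(cfg$read_len, mlen))
  reads2 <- NULL
  if (cfg$paired) {
    reads2 <- revcomp(substring(mol, pmax(1L, mlen - cfg$read_len + 1L), mlen))
  }

  # uniform sequencing errors
  add_errors <- function(reads) {
    if (cfg$seq_error_rate <= 0) return(reads)
    nerr <- rbinom(length(reads), nchar(reads), cfg$seq_error_rate)
    hit <- which(nerr > 0L)
    for (i in hit) {
      s <- reads[i]
      posns <- sample.int(nchar(s), nerr[i])
      for (p in posns) {
        substr(s, p, p) <- other_base(substring(s, p, p))
      }
      reads[i] <- s
    }
    reads
  }
  reads1 <- add_errors(reads1)
  if (!is.null(reads2)) reads2 <- add_errors(reads2)

  list(reads1 = reads1, reads2 = reads2, truth = truth, cfg = cfg)
}

#' Write simulated reads as FASTQ
#'
#' Constant Phred-30 qualities ("?") since the downstream pipeline ignores
#' base qualities; the simulation seed is recorded in each header.
#'
#' @param sim Output of [simulate_reads()].
#' @param file1 Path for mate-1 (or single-end) FASTQ.
#' @param file2 Path for mate-2 FASTQ (required when paired).
#' @export
write_sim_fastq <- function(sim, file1, file2 = NULL) {
  write_one <- function(reads, mate, file) {
    ids <- sprintf("mol%d/%d seed=%d", seq_along(reads), mate, sim$cfg$seed)
    qual <- vapply(nchar(reads), function(k)
      paste(rep("?", k), collapse = ""), character(1))
    con <- file(file, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  }
  write_one(sim$reads1, 1L, file1)
  if (!is.null(sim$reads2)) {
    if (is.null(file2)) stop("file2 required for paired reads", call. = FALSE)
    write_one(sim$reads2, 2L, file2)
  }
  invisible(NULL)
}

#' Read a FASTQ file as a character vector of sequences
#'
#' @param file FASTQ path.
#' @return Character vector of read sequences, named by record id.
#' @export
read_fastq_seqs <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  structure(as.character(x), names = names(x))
}

#' Cross-simulation configuration
#'
#' Founder germline allele fractions model mosaicism: different edits fixed in
#' different germ cells, so the fin genotype of a founder need not predict
#' transmission.
#'
#' @param founders Named list; each element is a named numeric vector of
#'   germline allele fractions for one founder (must include a `wild`
#'   component and sum to 1).
#' @param n_f1 Offspring per founder from an outcross to wild type.
#' @param f1_pairs Named list; each element a single allele label: an
#'   intercross of two heterozygotes for that allele.
#' @param n_f2 Offspring per intercross pair.
#' @param seed Integer seed.
#' @return An object of class `cross_sim_config`.
#' @export
cross_sim_config <- function(founders, n_f1 = 30L, f1_pairs = list(),
                             n_f2 = 100L, seed = 1L) {
  for (f in names(founders)) {
    fr <- founders[[f]]
    if (abs(sum(fr) - 1) > 1e-8)
      stop("allele fractions for founder ", f, " must sum to 1", call. = FALSE)
    if (!"wild" %in% names(fr))
      stop("founder ", f, " needs a 'wild' fraction (possibly 0)",
           call. = FALSE)
  }
  structure(list(founders = founders, n_f1 = as.integer(n_f1),
                 f1_pairs = f1_pairs, n_f2 = as.integer(n_f2),
                 seed = as.integer(seed)),
            class = "cross_sim_config")
}

#' Simulate founder -> F1 -> F2 crosses
#'
#' F1 genotypes are drawn by sampling one founder germline allele against a
#' wild maternal allele; an offspring is heterozygous for whichever non-wild
#' allele it inherits. F2 offspring of heterozygote intercrosses follow
#' Mendelian sampling (1/4 homozygous mutant, 1/2 heterozygous, 1/4 wild).
#' Deterministic for a fixed seed; truth labels are the genotype classes.
#'
#' @param cfg A [cross_sim_config()].
#' @return A list with `f1` (data.frame: `sample_id`, `founder_id`,
#'   `genotype_class`) and `f2` (data.frame: `sample_id`, `pair_id`,
#'   `genotype_class`, `affected` — TRUE for homozygous mutants).
#' @export
simulate_cross <- function(cfg) {
  stopifnot(inherits(cfg, "cross_sim_config"))
  set.seed(cfg$seed)
  f1_rows <- lapply(names(cfg$founders), function(f) {
    fr <- cfg$founders[[f]]
    allele <- sample(names(fr), cfg$n_f1, replace = TRUE, prob = fr)
    cls <- ifelse(allele == "wild", "wild", paste0(allele, " het"))
    data.frame(sample_id = paste0(f, "_F1_", seq_len(cfg$n_f1)),
               founder_id = f, genotype_class = cls,
               stringsAsFactors = FALSE)
  })
  f1 <- do.call(rbind, f1_rows)
  f2 <- NULL
  if (length(cfg$f1_pairs)) {
    f2_rows <- lapply(names(cfg$f1_pairs), function(p) {
      allele <- cfg$f1_pairs[[p]]
      g <- sample(c("hom", "het", "wild"), cfg$n_f2, replace = TRUE,
                  prob = c(0.25, 0.5, 0.25))
      cls <- c(hom = paste0(allele, " hom"), het = paste0(allele, " het"),
               wild = "wild")[g]
      data.frame(sample_id = paste0(p, "_F2_", seq_len(cfg$n_f2)),
                 pair_id = p, genotype_class = unname(cls),
                 affected = g == "hom", stringsAsFactors = FALSE)
    })
    f2 <- do.call(rbind, f2_rows)
  }
  list(f1 = f1, f2 = f2)
}
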