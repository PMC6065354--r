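test_that("find_pam_sites handles forced and impossible matches", {
  expect_equal(nrow(find_pam_sites("AAAA", pam_spec("NGG"))), 0L)
  hits <- find_pam_sites("ATGG", pam_spec("NGG"), both_strands = FALSE)
  expect_equal(hits$pam_start, 1L)
  expect_equal(hits$strand, "sense")
  expect_error(find_pam_sites("ATXG", pam_spec("NGG")), "non-DNA")
})

test_that("find_pam_sites equals a brute-force IUPAC scan on random sequences", {
  set.seed(101)
  for (rep in 1:10) {
    seq <- random_dna(200)
    pats <- c("NGG", "NAG")
    got <- find_pam_sites(seq, pam_spec(pats), both_strands = TRUE)
    want <- o_pam_scan(seq, pats, both_strands = TRUE)
    got_key <- sort(paste(got$pam_start, got$strand))
    want_key <- sort(paste(want$pos, want$strand))
    expect_equal(got_key, want_key)
  }
})

test_that("the default profile scores positions as published", {
  expect_equal(score_position(-18), 45)
  expect_equal(score_position(-19), 25)
  expect_equal(score_position(-15), 0)
  expect_equal(score_position(-21), 0)
  expect_equal(score_position(c(-20, -17, -16)), c(5, 35, 5))
})

test_that("the worked record yields exactly one fully specified candidate", {
  cds <- toy_stop_record()
  cand <- enumerate_stop_edits(cds)
  expect_equal(nrow(cand), 1L)
  expect_equal(cand$c_pos_in_record, 3L)
  expect_equal(cand$cds_c_number, 4L)
  expect_equal(cand$pam_relative_pos, -19L)
  expect_equal(cand$strand, "sense")
  expect_equal(cand$codon_before, "CAA")
  expect_equal(cand$codon_after, "TAA")
  expect_equal(cand$score, 25)
  expect_equal(cand$pam_seq, "TGG")
  # 18-nt spacer starts one base 3' of the target C (indices 4..21)
  expect_equal(cand$spacer_seq, substring(cds$seq, 5, 22))
  expect_equal(cand$other_window_cytosines, "")
})

test_that("ablating the PAM or breaking the codon removes the candidate", {
  cds <- toy_stop_record()
  seq2 <- cds$seq
  substr(seq2, 23, 25) <- "TTT"
  expect_equal(nrow(enumerate_stop_edits(coding_sequence("x", seq2, 0, 24))), 0L)
  # CAT -> TAT is Tyr, not stop
  seq3 <- cds$seq
  substr(seq3, 4, 6) <- "CAT"
  expect_equal(nrow(enumerate_stop_edits(coding_sequence("x", seq3, 0, 24))), 0L)
})

test_that("CDS frame violations are rejected", {
  expect_error(coding_sequence("x", strrep("A", 25), 0, 25), "multiple of 3")
  expect_error(coding_sequence("x", "ACGT", 2, 2), "out of bounds")
})

test_that("enumerate_stop_edits equals an exhaustive C x PAM oracle", {
  set.seed(202)
  for (rep in 1:8) {
    seq <- random_dna(300)
    cds <- coding_sequence("r", seq, 0, 300)
    got <- enumerate_stop_edits(cds)
    want <- o_enumerate(seq, 0, 300)
    got_key <- sort(paste(got$c_pos_in_record, got$pam_relative_pos,
                          got$strand, got$codon_before, got$codon_after))
    want_key <- sort(paste(want$c_pos, want$rel, want$strand, want$before,
                           want$after))
    expect_equal(got_key, want_key)
  }
})

test_that("edits create a stop exactly where reported, and only after editing", {
  set.seed(303)
  n_checked <- 0
  for (rep in 1:12) {
    seq <- random_dna(300)
    cds <- coding_sequence("r", seq, 0, 300)
    cand <- enumerate_stop_edits(cds)
    for (i in seq_len(nrow(cand))) {
      edited <- seq
      new_base <- if (cand$strand[i] == "sense") "T" else "A"
      substr(edited, cand$c_pos_in_record[i] + 1, cand$c_pos_in_record[i] + 1) <-
        new_base
      aa_before <- as.character(Biostrings::translate(
        Biostrings::DNAString(substring(seq, 1, 300)), no.init.codon = TRUE))
      aa_after <- as.character(Biostrings::translate(
        Biostrings::DNAString(substring(edited, 1, 300)), no.init.codon = TRUE))
      k <- cand$codon_index[i]
      expect_equal(substring(aa_after, k, k), "*")
      expect_false(substring(aa_before, k, k) == "*")
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 10)
})

test_that("sense candidates use CAA/CAG/CGA and antisense only TGG", {
  set.seed(404)
  befores_sense <- character(0); befores_anti <- character(0)
  for (rep in 1:10) {
    cand <- enumerate_stop_edits(coding_sequence("r", random_dna(300), 0, 300))
    befores_sense <- c(befores_sense, cand$codon_before[cand$strand == "sense"])
    befores_anti <- c(befores_anti, cand$codon_before[cand$strand == "antisense"])
  }
  expect_true(all(befores_sense %in% c("CAA", "CAG", "CGA")))
  expect_true(all(befores_anti == "TGG"))
  expect_gt(length(befores_sense), 0)
  expect_gt(length(befores_anti), 0)
})

test_that("scores are a pure function of PAM-relative position", {
  set.seed(505)
  cand <- enumerate_stop_edits(coding_sequence("r", random_dna(400), 0, 399))
  expect_equal(cand$score, score_position(cand$pam_relative_pos))
})

test_that("sense_only suppresses antisense candidates", {
  set.seed(606)
  for (rep in 1:5) {
    cds <- coding_sequence("r", random_dna(300), 0, 300)
    all_cand <- enumerate_stop_edits(cds)
    sense_cand <- enumerate_stop_edits(cds, sense_only = TRUE)
    expect_equal(sense_cand$c_pos_in_record,
                 all_cand$c_pos_in_record[all_cand$strand == "sense"])
  }
})

test_that("windows containing N are skipped and counted", {
  cds <- toy_stop_record()
  seq <- cds$seq
  substr(seq, 6, 6) <- "N"  # inside the editing window
  cand <- enumerate_stop_edits(coding_sequence("x", seq, 0, 24))
  expect_equal(nrow(cand), 0L)
  expect_gte(attr(cand, "n_skipped_N"), 1L)
})

test_that("spacer extraction follows the window/spacer relation", {
  cds <- toy_stop_record()
  sp18 <- spacer_for(cds, 22, "sense", 18)
  expect_equal(sp18, substring(cds$seq, 5, 22))
  expect_false(grepl("C", sp18))  # target C at -19 is outside an 18-nt spacer
  sp20 <- spacer_for(cds, 22, "sense", 20)
  expect_equal(substring(sp20, 2, 2), "C")  # a 20-nt spacer reaches it
  expect_error(spacer_for(cds, 10, "sense", 18), "runs off")
})

test_that("antisense spacers reverse-complement back onto the record", {
  set.seed(707)
  seq <- random_dna(100)
  sites <- find_pam_sites(seq, pam_spec("NGG"))
  anti <- sites[sites$strand == "antisense" & sites$pam_start <= 100 - 3 - 18, ]
  for (i in seq_len(min(nrow(anti), 5))) {
    p <- anti$pam_start[i]
    sp <- spacer_for(seq, p, "antisense", 18)
    expect_equal(o_revcomp(sp), substring(seq, p + 4, p + 21))
    expect_equal(o_revcomp(o_revcomp(sp)), sp)
  }
})

test_that("overlapping PAMs yield independent candidates for the same C", {
  # CAA codon with C in window of two overlapping PAMs: ...C at -17 of PAM1
  # and -16 of PAM2 (PAMs at offsets differing by 1, e.g. AGG at i and GGG at i+1)
  seq <- paste0("ATG", "CAA", strrep("A", 10), "AGGG", strrep("A", 4))
  # PAM candidates: AGG at index 16, GGG at index 17
  cds <- coding_sequence("dup", seq, 0, 21)
  cand <- enumerate_stop_edits(cds, window = c(-20, -10), spacer_len = 3)
  same_c <- cand[cand$c_pos_in_record == 3 & cand$strand == "sense", ]
  expect_gte(nrow(same_c), 2)
  expect_true(length(unique(same_c$pam_relative_pos)) >= 2)
})

test_that("FASTA + locus table round-trips into coding_sequence records", {
  fa <- tempfile(fileext = ".fa")
  loci <- tempfile(fileext = ".tsv")
  cds <- toy_stop_record()
  writeLines(c(">toy", cds$seq), fa)
  write.table(data.frame(id = "toy", cds_start = 0, cds_end = 24),
              loci, sep = "\t", quote = FALSE, row.names = FALSE)
  recs <- read_coding_sequences(fa, loci)
  expect_equal(recs$toy$seq, cds$seq)
  expect_equal(recs$toy$cds_end, 24L)
  cand <- enumerate_stop_edits(recs$toy)
  expect_equal(cand$cds_c_number, 4L)
})
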