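# Shared fixtures built in code.

# The 24-codon-less worked record: ATGCAA, 16 adenines, then a TGG PAM at
# index 22. CDS = first 24 bases (8 codons); the lone window cytosine sits at
# record index 3, PAM-relative -19.
toy_stop_record <- function() {
  seq <- paste0("ATGCAA", strrep("A", 16), "TGG")
  coding_sequence("toy", seq, cds_start = 0, cds_end = 24)
}

# A random amplicon with a forced sense-strand NGG PAM and a C at -19,
# mirroring the structure of a base-editing target locus.
make_target_amplicon <- function(len = 250L, pam_start = 180L, seed = 7L) {
  set.seed(seed)
  ref <- random_dna(len)
  substr(ref, pam_start + 1L, pam_start + 3L) <- "TGG"
  substr(ref, pam_start - 19L + 1L, pam_start - 19L + 1L) <- "C"
  list(ref = ref, pam_start = pam_start)
}
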