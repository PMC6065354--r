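
# a reproducible 400-nt template with a C>T variant at index 200
aspcr_fixture <- function(seed = 1, len = 400, idx = 200) {
  set.seed(seed)
  ref <- random_dna(len)
  substr(ref, idx + 1, idx + 1) <- "C"
  list(ref = ref, snv = list(idx, "C", "T"))
}

test_that("forward designs put the allele on the 3' terminus and one engineered mismatch", {
  fx <- aspcr_fixture()
  d <- design_as_primers(fx$ref, fx$snv, primer_len = 20,
                         orientation = "forward", product_len_target = 150,
                         control = FALSE)
  expect_equal(substring(d$wild_primer, 20, 20), "C")
  expect_equal(substring(d$mut_primer, 20, 20), "T")
  # identical except the terminal base
  expect_equal(substring(d$wild_primer, 1, 19), substring(d$mut_primer, 1, 19))
  # exactly one further difference vs the reference: the engineered mismatch
  # at offset 2 from the 3' end
  ref_window <- substring(fx$ref, 200 - 18, 200 + 1)
  diffs <- which(strsplit(d$wild_primer, "")[[1]] !=
                   strsplit(ref_window, "")[[1]])
  expect_equal(diffs, 18L)  # primer position 18 = offset 2 from the 3' end
  expect_equal(d$engineered_mismatch_offset, 2L)
  expect_lte(abs(d$wild_tm - d$mut_tm), 2)
})

test_that("reverse designs mirror the alleles as G (wild) and A (mutant)", {
  fx <- aspcr_fixture()
  d <- design_as_primers(fx$ref, fx$snv, primer_len = 20,
                         orientation = "reverse", product_len_target = 150,
                         control = FALSE)
  expect_equal(substring(d$wild_primer, 20, 20), "G")
  expect_equal(substring(d$mut_primer, 20, 20), "A")
  expect_equal(substring(d$wild_primer, 1, 19), substring(d$mut_primer, 1, 19))
})

test_that("a disagreeing snv ref_base is rejected", {
  fx <- aspcr_fixture()
  expect_error(design_as_primers(fx$ref, list(200, "G", "A")),
               "does not match")
  near_base <- substring(fx$ref, 6, 6)
  expect_error(design_as_primers(fx$ref, list(5, near_base, "T"),
                                 primer_len = 20),
               "too close")
})

test_that("the control amplicon sits 800-1400 bp downstream", {
  set.seed(2)
  ref <- random_dna(2000)
  substr(ref, 201, 201) <- "C"
  d <- design_as_primers(ref, list(200, "C", "T"), control_offset = 900,
                         control_len = 400)
  expect_gte(d$control_start - 200, 800)
  expect_lte(d$control_start - 200, 1400)
  prods <- in_silico_pcr(ref, d$control_fwd, d$control_rev)
  expect_equal(prods, 400L)
  expect_error(design_as_primers(ref, list(200, "C", "T"),
                                 control_offset = 500), "control_offset")
})

test_that("in-silico PCR amplifies the designed pair and honours the 3' rule", {
  fx <- aspcr_fixture()
  d <- design_as_primers(fx$ref, fx$snv, orientation = "forward",
                         product_len_target = 150, control = FALSE)
  mut_ref <- fx$ref
  substr(mut_ref, 201, 201) <- "T"
  expect_equal(in_silico_pcr(fx$ref, d$wild_primer, d$shared_primer), 150L)
  expect_equal(length(in_silico_pcr(fx$ref, d$mut_primer, d$shared_primer)), 0L)
  expect_equal(in_silico_pcr(mut_ref, d$mut_primer, d$shared_primer), 150L)
  expect_equal(length(in_silico_pcr(mut_ref, d$wild_primer, d$shared_primer)), 0L)
})

test_that("in-silico PCR matches a brute-force binding-site oracle", {
  set.seed(3)
  for (rep in 1:20) {
    tmpl <- random_dna(300)
    # primers lifted from the template with occasional internal mutations
    f0 <- sample(1:100, 1)
    fwd <- substring(tmpl, f0, f0 + 17)
    r0 <- sample(180:260, 1)
    rev <- o_revcomp(substring(tmpl, r0, r0 + 17))
    if (rep %% 2 == 0) {
      p <- sample(2:16, 1)  # internal only
      substr(fwd, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    got <- in_silico_pcr(tmpl, fwd, rev, max_internal_mismatches = 2)
    # oracle: scan every fwd/rev placement
    tc <- strsplit(tmpl, "")[[1]]
    sites <- function(primer, term_at_start) {
      pc <- strsplit(primer, "")[[1]]
      hits <- integer(0)
      for (s in 0:(300 - 18)) {
        win <- tc[(s + 1):(s + 18)]
        mism <- win != pc
        ti <- if (term_at_start) 1 else 18
        if (mism[ti]) next
        if (sum(mism[-ti]) > 2) next
        hits <- c(hits, s)
      }
      hits
    }
    want <- integer(0)
    for (f in sites(fwd, FALSE)) {
      for (r in sites(o_revcomp(rev), TRUE)) {
        if (r >= f + 18) {
          len <- r + 18 - f
          if (len <= 5000) want <- c(want, len)
        }
      }
    }
    expect_equal(got, sort(want), info = paste("rep", rep))
  }
})

test_that("every generated design discriminates alleles in silico", {
  set.seed(4)
  n_ok <- 0
  for (rep in 1:100) {
    ref <- random_dna(400)
    idx <- sample(100:300, 1)
    ref_base <- substring(ref, idx + 1, idx + 1)
    alt_base <- sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)
    orientation <- sample(c("forward", "reverse"), 1)
    d <- design_as_primers(ref, list(idx, ref_base, alt_base),
                           orientation = orientation,
                           product_len_target = 90, control = FALSE)
    v <- verify_as_primers(d, ref)
    matched <- v$amplifies[v$allele_primer == v$template]
    crossed <- v$amplifies[v$allele_primer != v$template]
    expect_true(all(matched), info = paste("rep", rep))
    expect_false(any(crossed), info = paste("rep", rep))
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 100)
})

test_that("designing on the reverse-complemented reference mirrors the primers", {
  fx <- aspcr_fixture()
  n <- nchar(fx$ref)
  d_f <- design_as_primers(fx$ref, fx$snv, orientation = "forward",
                           product_len_target = 120, control = FALSE)
  rc_ref <- o_revcomp(fx$ref)
  rc_snv <- list(n - 1 - fx$snv[[1]], "G", "A")
  d_r <- design_as_primers(rc_ref, rc_snv, orientation = "reverse",
                           product_len_target = 120, control = FALSE)
  expect_equal(d_r$wild_primer, d_f$wild_primer)
  expect_equal(d_r$mut_primer, d_f$mut_primer)
})
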