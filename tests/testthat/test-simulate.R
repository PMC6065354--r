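test_that("all-zero rates yield perfect reference fragments", {
  amp <- make_target_amplicon()
  cfg <- read_sim_config(amp$ref, amp$pam_start, sub_rates = NULL,
                         indel_rate = 0, seq_error_rate = 0,
                         n_reads = 50, seed = 5)
  sim <- simulate_reads(cfg)
  expect_true(all(sim$reads1 == substring(amp$ref, 1, 151)))
  expect_true(all(sim$reads2 ==
                    o_revcomp(substring(amp$ref, 100, 250))))
  expect_false(any(sim$truth$indel))
})

test_that("the same seed reproduces the read set byte for byte", {
  amp <- make_target_amplicon()
  cfg <- read_sim_config(amp$ref, amp$pam_start,
                         sub_rates = data.frame(pos = -19, alt = "T",
                                                rate = 0.05),
                         indel_rate = 0.02, n_reads = 500, seed = 42)
  s1 <- simulate_reads(cfg)
  s2 <- simulate_reads(cfg)
  expect_identical(s1$reads1, s2$reads1)
  expect_identical(s1$reads2, s2$reads2)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- read_sim_config(amp$ref, amp$pam_start,
                          sub_rates = data.frame(pos = -19, alt = "T",
                                                 rate = 0.05),
                          indel_rate = 0.02, n_reads = 500, seed = 43)
  expect_false(identical(simulate_reads(cfg2)$reads1, s1$reads1))
})

test_that("short fragments are positioned uniformly and edits track coverage", {
  amp <- make_target_amplicon()
  cfg <- read_sim_config(amp$ref, amp$pam_start,
                         sub_rates = data.frame(pos = -19, alt = "T",
                                                rate = 0.5),
                         fragment_len = 200L, seq_error_rate = 0,
                         n_reads = 2000, seed = 9)
  sim <- simulate_reads(cfg)
  expect_true(all(sim$truth$frag_start >= 0 &
                    sim$truth$frag_start <= 250 - 200))
  expect_gt(length(unique(sim$truth$frag_start)), 10)
  # edits recorded only on fragments covering the -19 site
  idx0 <- amp$pam_start - 19L
  covered <- idx0 >= sim$truth$frag_start &
    idx0 < sim$truth$frag_start + 200L
  expect_false(any(sim$truth$`sub_-19_T` & !covered))
  expect_lt(abs(mean(sim$truth$`sub_-19_T`[covered]) - 0.5),
            3 * sqrt(0.25 / sum(covered)))
  expect_error(read_sim_config(amp$ref, amp$pam_start, fragment_len = 50,
                               n_reads = 5),
               "fragment_len")
})

test_that("contradictory per-position rates are a config error", {
  amp <- make_target_amplicon()
  bad <- data.frame(pos = c(-19, -19), alt = c("T", "A"), rate = c(0.7, 0.5))
  expect_error(read_sim_config(amp$ref, amp$pam_start, sub_rates = bad,
                               n_reads = 10),
               "sum to more than 1")
})

test_that("truth-table rates match configured rates within 3 SE over seeds", {
  amp <- make_target_amplicon()
  rates <- data.frame(pos = c(-19, -16), alt = c("T", "T"),
                      rate = c(0.05, 0.02))
  n <- 4000L
  for (seed in 1:20) {
    cfg <- read_sim_config(amp$ref, amp$pam_start, sub_rates = rates,
                           indel_rate = 0.01, n_reads = n, seed = seed)
    truth <- simulate_reads(cfg)$truth
    for (j in seq_len(nrow(rates))) {
      p <- rates$rate[j]
      got <- mean(truth[[sprintf("sub_%d_T", rates$pos[j])]])
      expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / n) + 1e-12,
                label = sprintf("seed %d pos %d", seed, rates$pos[j]))
    }
    expect_lt(abs(mean(truth$indel) - 0.01),
              3 * sqrt(0.01 * 0.99 / n) + 1e-12)
  }
})

test_that("FASTQ output round-trips and records the seed", {
  amp <- make_target_amplicon()
  cfg <- read_sim_config(amp$ref, amp$pam_start,
                         sub_rates = data.frame(pos = -19, alt = "T",
                                                rate = 0.1),
                         n_reads = 30, seed = 8)
  sim <- simulate_reads(cfg)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_sim_fastq(sim, f1, f2)
  back1 <- read_fastq_seqs(f1)
  back2 <- read_fastq_seqs(f2)
  expect_equal(unname(back1), sim$reads1)
  expect_equal(unname(back2), sim$reads2)
  expect_true(all(grepl("seed=8", names(back1))))
})

test_that("a fully wild founder germline gives only wild F1", {
  cfg <- cross_sim_config(founders = list(g0 = c(wild = 1.0)), n_f1 = 50,
                          seed = 3)
  expect_true(all(simulate_cross(cfg)$f1$genotype_class == "wild"))
})

test_that("het x het F2 homozygote fraction is binomial around 25%", {
  cfg <- cross_sim_config(founders = list(g0 = c(`c.232C>T` = 0.5,
                                                 wild = 0.5)),
                          n_f1 = 10,
                          f1_pairs = list(p1 = "c.232C>T"), n_f2 = 10000,
                          seed = 21)
  f2 <- simulate_cross(cfg)$f2
  hom <- mean(f2$affected)
  expect_lt(abs(hom - 0.25), 3 * sqrt(0.25 * 0.75 / 10000))
  expect_equal(unique(f2$genotype_class[f2$affected]), "c.232C>T hom")
})

test_that("mosaic founder germline fractions surface as F1 het fractions", {
  cfg <- cross_sim_config(founders = list(g0 = c(`c.232C>T` = 0.3,
                                                 wild = 0.7)),
                          n_f1 = 5000, seed = 31)
  f1 <- simulate_cross(cfg)$f1
  het <- mean(f1$genotype_class == "c.232C>T het")
  expect_lt(abs(het - 0.3), 3 * sqrt(0.3 * 0.7 / 5000))
})
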