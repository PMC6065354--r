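---
title: "Designing and quantifying stop-codon-introducing base edits with stopkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and quantifying stop-codon-introducing base edits with stopkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stopkit)
```

## The experimental system

Cytidine-deaminase base editors (Target-AID and relatives) tether PmCDA1 to a
catalytically disabled Cas9 (dCas9) or a D10A nickase (nCas9). Guided by an
sgRNA, the deaminase converts cytosines to uracil within a narrow window 5' of
the protospacer, which is fixed as a C-to-T transition after replication — no
double-strand break is made. Aimed at a codon where a C>T creates TAA, TAG or
TGA, this yields programmable premature stop codons, and in a vertebrate
germline the edits are heritable: founders are mosaics, F1 heterozygotes carry
single edited alleles, and F2 intercross offspring segregate the recessive
phenotype at the Mendelian quarter.

stopkit implements the computational arms of such an experiment: target
design, off-target enumeration, quantification of editing outcomes from
amplicon deep sequencing, allele-specific PCR (ARMS) genotyping design, and
inheritance arithmetic — plus a synthetic-data generator so the entire
pipeline can be exercised and validated without any sequencing run.

## Coordinate conventions

All internal coordinates are 0-based and half-open. Reports use the 1-based
"c." numbering for coding positions, as genotyping papers do (e.g. c.232C>T).
PAM-relative positions count backwards from the PAM: position −1 is the base
immediately 5' of the PAM's first base, so an 18-nt spacer occupies −18..−1
and the editing window sits at −20..−16. A target cytosine at −19 or −20
therefore lies *outside* an 18-nt spacer; that is legal and is exactly the
geometry of a −19 target with an 18-nt guide.

## Target design

`enumerate_stop_edits()` scans a `coding_sequence()` (sequence plus explicit
CDS offsets — intron/exon structure is carried by the offsets, so spacers may
span splice junctions) for cytosines in the editing window whose C>T creates
a stop. The genetic code forces the candidate codons: on the sense strand
only CAA→TAA, CAG→TAG and CGA→TGA work (the C at codon position 1); on the
antisense strand only tryptophan TGG codons can yield a stop, via G>A on the
coding strand at codon position 2 or 3. Antisense candidates are enumerated
by default but flagged by strand, and `sense_only = TRUE` restricts the scan
to direct C>T designs.

Each candidate is scored with a position-wise `efficiency_profile()`. The
default profile is the published yeast estimate for the −20..−16 window:
roughly 5, 25, 45, 35 and 5 percent deamination at −20, −19, −18, −17 and
−16. Positions −21 and −22 are tabulated by the spectrum module but default
to zero efficiency, since there is no evidence they edit. Scores are a pure
function of PAM-relative position; they rank designs and set expectations,
nothing more.

Design decisions worth making explicit:

* Overlapping PAMs each generate independent candidates for the same
  cytosine — the same C can be editable from two PAMs at different window
  positions with different expected efficiencies, and deduplicating would
  hide the better design.
* Bystander cytosines (other window Cs) are listed per candidate, never
  filtered: co-editing risk is a judgement call for the designer.
* Windows or codons containing N are skipped, with a skip count attached to
  the result, rather than guessed at.

```{r design}
cds <- coding_sequence("toy", paste0("ATGCAA", strrep("A", 16), "TGG"),
                       cds_start = 0, cds_end = 24)
enumerate_stop_edits(cds)
```

## Off-target enumeration

`scan_offtargets()` is an exhaustive Hamming-distance scan: every NGG (and
optionally NAG) PAM occurrence on both strands of every subject is tested
against the spacer, keeping sites within `max_mismatches` (default 4,
matching the 1–4-mismatch range a genome-wide predictor reports for typical
guides). No bulges are modelled — mismatch counting only, which keeps the
enumeration exact and oracle-checkable. Output is sorted by mismatch count
then coordinate; `rank_offtargets()` additionally orders ties by how far the
mismatches sit from the PAM, since PAM-proximal ("seed") mismatches suppress
activity and make a site lower-risk. This scanner is intended for
amplicon/contig-scale subjects, not genome-wide indexing.

## Amplicon spectrum: alignment, filters, tabulation

The quantification core re-implements, as explicit dynamic programming, the
mapping parameterisation used by commercial amplicon pipelines: semi-global
alignment (the read aligns end-to-end against an internal span of the
reference, reference overhangs free) with mismatch cost 2, insertion cost 3
and deletion cost 3 per base. Cost ties prefer a mismatch over a gap — with
these costs a single mismatch (2) is always cheaper than a single-base gap
(3), which the alignment tests pin down. Reads must align at least 50% of
their length and reach 80% identity over aligned columns to pass
(`alignment_params()`).

Variant reporting applies three gates (`variant_filter()`): coverage ≥ 10,
supporting count ≥ 2 and frequency ≥ 0.5%. Sub-threshold observations stay
in the raw counts, flagged unreported, so the conservation invariant — at
every position the class counts sum to the coverage — always holds on raw
counts.

Paired 151-bp mates are handled by aligning each mate independently and
counting each fragment once per covered position; where mates overlap, mate
1's call wins (the data carry no base qualities, so a fixed precedence is
the reproducible choice). An "indel-containing read" is any passing fragment
whose alignment contains at least one insertion or deletion operation
anywhere in the amplicon — the indel estimate is deliberately per-read, not
per-position.

`mutation_spectrum()` re-indexes the filtered pileup onto the PAM-relative
−22..−1 axis and reports per-position substitution and deletion frequencies
to 2 decimals. `substitution_indel_ratio()` computes the purity measure:
targeted C>T frequency divided by indel frequency, e.g. 2.19/0.91 → 2.41 and
4.37/8.48 → 0.52. With zero indels the ratio is reported as infinite with a
flag rather than an error.

One published ratio (an oep nickase value of 0.97) is not derivable from its
printed inputs (1.04/1.17 = 0.89); because the convention that produced it
is unstated, the function takes explicit `target_positions` so any
convention can be computed, and that value is not used as a reference point
anywhere in the tests.

## Allele-specific PCR design

`design_as_primers()` follows the classic ARMS recipe: the allele-specific
primers place their 3'-terminal base on the variant (wild-type primer ends
in the reference base, mutant primer in the edited base — or their
complements for a reverse-orientation design, where a C>T edit yields wild G
/ mutant A), and one additional destabilizing mismatch is engineered two
bases from the 3' end of both. The engineered base prefers T, falling back
to the most destabilizing mismatch class (purine–purine >
pyrimidine–pyrimidine > wobble). Melting temperatures use the Wallace rule
(2 °C per A/T, 4 °C per G/C) — the two allele primers differ only at the
terminal base, so their Tm difference is at most 2 °C by construction;
nearest-neighbour thermodynamics would add precision the design rule does
not need. An internal-control pair amplifies a region 800–1400 bp downstream
of the variant, so every reaction has a product regardless of genotype.

`in_silico_pcr()` verifies designs: binding sites allow internal mismatches
(default 2 — one is consumed by the engineered mismatch) but zero
3'-terminal mismatches, which is precisely the ARMS discrimination
mechanism. The property test asserts, over random references and variants,
that every generated design amplifies the matched allele and never the
mismatched one. Published product sizes from any particular genotyping gel
depend on unpublished primer placements and are not design targets; products
are sized by the user's `product_len_target`.

## Inheritance arithmetic

`tally_genotypes()` turns genotype-class labels into counts and percentages
(1 decimal, matching how genotype panels are reported — e.g. 10/34 → 29.4%).
`segregation_test()` is the textbook two-class goodness-of-fit chi-square
against an expected affected fraction (default the recessive 1/4), without
Yates correction by default (a correction flag exists); the statistic is
cross-checked against `stats::chisq.test` in the tests. `transmission_rate()`
counts a founder as transmitting when any offspring class is non-wild —
which correctly classifies the instructive real-world case of a mosaic
founder whose fin genotype shows an edit but whose germline transmits
nothing.

## Synthetic data

The generator exists so every stage is testable end-to-end with known truth.
`simulate_reads()` draws molecules of a reference amplicon (by default each
fragment is the whole amplicon — the PCR model; a shorter `fragment_len`
positions fragments uniformly instead), applies true
edits per molecule (mutually exclusive per position), places indels
(single-base with a geometric tail, default success probability 0.7) at
uniform positions within the protospacer ±5 — the editor's footprint, since
the real data do not localize indels more precisely — cuts 151-bp single or
paired reads (mate 2 reverse-complemented, as sequencers emit it), and
overlays uniform per-base sequencing error (default 0.001, a typical
post-filter short-read error rate). A truth table of per-molecule edits is
returned so recovery can be scored exactly. Simulations are deterministic
per seed, with the seed recorded in FASTQ headers. Qualities are constant
Phred 30 because the pipeline ignores them.

The default study condition mirrors the published chd dCas9 experiment: a
250-nt amplicon, targeted C>T at −19 at 2.19%, per-read indels at 0.91%,
200,000 paired fragments. At that depth the binomial standard error of the
C>T estimate is ~0.033 percentage points; the acceptance check requires
recovery within 3 standard errors of the configured truth. Note one honest
bias: uniform sequencing error contributes ~0.001/3 ≈ 0.03% apparent C>T at
every C, which consumes part of that band. Per-embryo rate variation (real
experiments pool embryos) is not modelled; reads are pooled, as the
published per-locus tables are.

`simulate_cross()` models the generational structure: founder germlines as
allele-fraction mixtures (mosaicism), F1 from outcrosses to wild type, F2
from heterozygote intercrosses with 1:2:1 Mendelian sampling.

What passing these tests shows — and does not show: the pipeline recovers
known rates from data generated under its own error model (uniform errors,
no quality structure, no PCR duplicates or chimeras, fragment = amplicon).
Real amplicon data violate all of these mildly; the filter thresholds
(coverage/count/frequency) are the standard defence, but performance on real
libraries is a claim this package's tests do not make.

## Problem sizes and numerical choices

The test suite runs the full 200,000-fragment recovery experiment plus
oracle cross-checks (full-matrix alignment DP, exhaustive design and
off-target scans, 100 random ARMS instances) in about a minute on one CPU.
The alignment core short-circuits to an ungapped scan when the best ungapped
cost is at most 3: since any gap costs at least 3 and ties prefer
mismatches, such an alignment is provably optimal, so the shortcut is exact,
not heuristic — the oracle-equivalence tests cover both code paths.
Tie-breaking in traceback prefers diagonal moves, then insertions, giving
deterministic CIGARs; only costs are contract, and only costs are
oracle-tested.

## Known limitations

* Hamming-only off-target model; no bulges, no genome-scale index.
* No base-quality modelling anywhere; mate-overlap resolution is positional,
  not quality-weighted.
* Wallace-rule Tm only; no secondary-structure or dimer thermodynamics.
* The efficiency profile is a fixed lookup, not a learned model.
* Genotype classes are free-text labels from upstream callers; the
  inheritance module never re-calls genotypes.
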