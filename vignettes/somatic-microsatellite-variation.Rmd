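---
title: "Calling somatic microsatellite variation from tumor-only sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic microsatellite variation from tumor-only sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smvtools)
```

## The problem

Microsatellites (MSTs) — tandem repeats of 1–6 nt motifs — mutate 10–1000×
faster than flanking DNA, predominantly by polymerase slippage that expands
or contracts the repeat by whole motif units ("in-phase" INDELs). In a
sequenced cell population, subclonal slippage events appear as low-frequency
alleles that do not belong to the sample's one- or two-allele genotype.
`smvtools` quantifies this **somatic microsatellite variation (SMV)** from a
single aligned sample, with no matched normal: it genotypes every
catalogued repeat, then calls the residual "minor" alleles, classifies them
(SNP / expansion / contraction, in- or out-of-phase), and summarizes their
abundance, genomic distribution and cross-sample concordance. Because minor
alleles live at frequencies comparable to sequencing error, the package
also ships a read simulator whose planted ground truth is used to
characterize the error regime and to validate the caller end to end.

## The caller's model

At each catalogued locus, a read contributes one observation when it

1. fully spans the repeat plus a fixed-length flank anchor on each side
   (`flank_length`, default 5 nt; 7 also common),
2. has mapping quality ≥ 10,
3. has every base quality inside the repeat ≥ 28, and
4. matches both flank anchors exactly.

The allele is the read substring between the anchors, so indels inside the
repeat change its length. Distinct allele sequences are binned with
strand-aware support; an allele is *called* when it has at least
`min_reads_per_allele` supporting reads (default 3; 2 and 4 supported) seen
on both strands. Loci with fewer than 15 retained reads are left
ungenotyped.

The most common called allele is always a haplotype allele. The second most
common joins the haplotype — a heterozygous call — iff its support exceeds
25% of the reads supporting called alleles at the locus, or 50% of the
major allele's support. Every other called allele is a minor allele, the
unit of SMV.

Two points where the published rule set is ambiguous, and the choices made
here:

* **Denominator of the 25% rule.** We use the total of reads supporting
  *called* alleles, not all retained reads. Retained reads whose repeat
  bases carry errors support no allele; counting them inflates the
  denominator and symmetrically deflates both haplotype classes, so that at
  a 5% per-base error rate the expected second-allele share falls below the
  25% threshold and true heterozygotes would be systematically dropped —
  incompatible with the near-perfect zygosity accuracy this design is known
  to achieve on simulated data. With the binned-read denominator the
  heterozygote decision depends on the allele *ratio*, which is robust to
  error attrition. The ungenotyped cutoff (15) still uses retained reads.
* **Anchor location.** A 5-mer recurs by chance in a 100-nt read about 9%
  of the time, so the left anchor is located at the occurrence closest to
  its alignment-predicted offset (overlapping occurrences included), and
  the right anchor at the first occurrence after it. "Both directions" is
  read as strand duality (≥1 forward and ≥1 reverse read), with
  `both_strand_required = FALSE` available; anchors may optionally tolerate
  one mismatch (`allow_flank_mismatch = 1`), off by default.

## The catalogue

`scan_tandem_repeats()` is a built-in seed-and-extend detector, not a
re-implementation of Tandem Repeats Finder: candidates are seeded by exact
tandem cores (≥ 2 copies and ≥ max(2·motif, 4) nt of a primitive unit),
extended base by base under the seed's periodic template while the match
fraction stays at or above the purity floor — stopping once two consecutive
mismatches accumulate at the growing end — and trimmed of terminal
mismatches. **Purity** is the fraction of positions matching the best-phase
perfect repetition of the motif (maximum over rotations, ungapped): a
deterministic, oracle-checkable quantity. Filtering keeps loci ≥ 8 nt with
≥ 3 motif copies and purity ≥ 0.85; overlaps resolve by higher purity, then
length, then leftmost start, a total order that makes the catalogue
deterministic. Motifs are reported as their lexicographically minimal
rotation, and when several motif lengths fit an interval the shortest wins
(so copy counts stay meaningful). Coordinates are 0-based half-open
throughout; the TSV catalogue doubles as BED3+. The exact-core seed rule is
a sensitivity heuristic: a long, heavily mosaic repeat whose longest clean
stretch is under two motif copies can be missed. Such loci are rare in real
catalogues and absent from the simulator's planted references.

Matched non-repeat control loci (`sample_non_mst_loci()`) are fixed 15-nt
segments drawn uniformly over the mappable reference, excluding anything
that intersects the catalogue, so the same pipeline can be run on
non-repeat DNA for comparison.

## The simulator and its study conditions

`simulate_sample()` plants perfect repeats (motif lengths 1–6, weighted
0.40/0.25/0.15/0.10/0.06/0.04 toward short motifs, as in genomic repeat
spectra) separated by 400 nt random flanks on a synthetic chromosome, and
generates 2×100 bp paired-end reads:

* **Locus lengths 8–44 nt**, with copy numbers decaying geometrically above
  the minimum (P ≈ 0.25 per extra copy): genomic MST length spectra are
  strongly short-skewed, and very long homopolymers would otherwise be
  heavily over-represented.
* **Coverage**: each locus draws its spanning-read depth from a
  gamma-Poisson mixture (`mean_depth` 50, gamma shape 10), the
  "overdispersed" mode emulating real capture data; a near-uniform Poisson
  ("wgsim-like") mode is also available. Mates are placed 300 nt away in
  the flank, so spanning depth equals the draw and a mate never spans a
  neighbouring locus.
* **Genotypes**: 5% of loci are heterozygous with a second allele 1–2 motif
  units longer or shorter (in phase); optionally, loci receive one
  subclonal minor allele at a read fraction drawn from 0.05–0.15, below
  the heterozygote threshold.
* **Errors**: per-base error 0.5–5%, split 90:10 between substitutions and
  1-nt indels. The 90:10 mix was chosen from a coarse grid (1/2/5/10%
  indels) as the one whose *called* false-allele spectrum is SNP-dominated
  at the level expected for this class of generator (~90% SNP alleles);
  smaller indel shares overshoot the SNP fraction. Base qualities are
  constant (35) and error positions are *not* marked low-quality by default
  (`error_low_quality_prob = 0`), so read-count thresholds can be studied
  in isolation from quality filtering.
* Flank bases adjacent to each locus are forced to break the repeat phase
  (3 nt) and the 7-nt anchor regions are kept out of the repeat's periodic
  sequence, so planted boundaries are recovered exactly by the scanner and
  anchors are unambiguous in reads. Incidental short repeats deeper inside
  the random flanks are left in place — real genomes have them — but they
  are excluded from a planted locus's neighbourhood (10 nt margin) and are
  not part of the emitted catalogue.

Alignment is bypassed by construction (records carry correct positions,
flags and CIGARs), so the simulator characterizes caller behaviour, not
aligner behaviour; mapping error, PCR duplicates and whole-genome
amplification artifacts are out of its scope. Consequently, passing the
simulation study shows the *rules* behave as designed under known coverage
and error; it does not bound misalignment-driven artifacts in real exomes.

With these conditions the regenerated error study gives: zygosity accuracy
99.95–99.0% from 0.5% to 5% error (the design target for this rule
set is >99.98% at every rate; the residual gap comes from low-coverage
heterozygotes missing the 3-read/both-strand requirement and, at ≥2.5%
error, pooled 1-nt deletion errors at long homopolymers crossing the
50%-of-major rule — both intrinsic to the rule set once error bases keep
high base qualities); loci free of false alleles at 1% error: ~98.5% with 3
reads and ~99.8% with 4; at 5% error with 3 reads: ~92%, above the 73% design
floor for this regime. Raising the threshold can only remove
alleles (a tested monotonicity invariant), mirroring the 2→3→4-read
progression.

## Profile statistics

* `sample_summary()`: percent homozygous / heterozygous (summing to 100
  over genotyped loci) and percent of loci with ≥1 minor allele.
* `variant_spectrum()`: SNP / expansion / contraction percentages among
  minor alleles (second haplotype alleles can be included with
  `scope = "all_non_major"`); the in-phase percentage is reported over
  INDEL alleles. An allele differing in both length and content counts by
  its length change; same-length alleles with several substitutions count
  once as SNP-class (alleles, not events, are counted).
* `bin_minor_fractions()` + `hotspot_bins()`: minor-allele locus fractions
  per chromosome and per 1-Mb bin; a bin is a hotspot when its one-cell
  1-df goodness-of-fit statistic against the genome-wide rate exceeds the
  upper-tail `alpha = 0.01` point *and* the bin is in excess. No
  multiple-testing correction by default (matching the visual-threshold
  usage this statistic supports); `bonferroni = TRUE` divides alpha by the
  number of testable bins.
* `compare_samples()`: over loci genotyped in both samples — genotype
  discordance (haplotype allele sets differ), split into threshold-boundary
  cases (same allele sequences, only the heterozygote classification
  differs; the dominant mode between replicates) versus true sequence
  differences; and the three minor-allele categories (both / exactly one /
  neither), which sum to 100 by construction. The categories are defined
  disjoint, so they always sum to exactly 100.
* `concordance_null()`: the random-overlap expectation is the product of
  the per-sample minor fractions (5.4% × 5.3% → 0.2862%), reported
  alongside an optional Monte-Carlo subset null and a Pearson 1-df
  goodness-of-fit test of the observed concordant count. The analytic
  product is reported as-is, with no looser approximation substituted.
* `second_allele_read_fractions()`, `between_sample_regression()`,
  `region_partition_summary()`: read-fraction summaries over minor-bearing
  loci, OLS comparison of paired per-chromosome/bin fractions, and the
  exon-versus-untranslated partition (a locus is exonic on any ≥1 bp
  overlap — the conservative reading for "exonal" repeats) with a
  gene-level report of loci carrying ≥2 minor alleles, including
  per-sample presence counts when several call sets are given.
  Cross-sample z-tests and outlier tests are not re-implemented; the
  summaries expose the proportions and counts needed to run them with
  standard tools.

## Numerical and degenerate-input conventions

Heterozygote inequalities are strict. Allele ordering is by
support, then longer length, then lexicographic sequence — a total order,
so repeated runs are byte-identical. Uncalled loci carry a reason code
(`low_depth` vs `no_alleles`). Empty inputs return typed empty frames;
zero classifiable alleles and zero qualifying loci return flagged empty
summaries rather than NaNs. All randomness flows from a single integer
seed per simulation (stage offsets +1, +2), and every randomized operation
takes an explicit seed.

## Problem sizes used in the checks

The packaged tests regenerate the study at 2,000 loci per error rate
(mean depth 50), use 400–5,000-locus simulations for identity,
parameter-recovery and monotonicity properties, 10,000 random pileups for
the rule-transcription oracle, and small hand-built fixtures for every
worked example. `scripts/acceptance.R` re-runs the four-rate study from
scratch at 2,000 loci per rate.

## Known limitations

* The detector is an explicit approximation: it does not reproduce Tandem
  Repeats Finder's alignment scoring, so catalogue counts on a real genome
  will differ from TRF-derived catalogues.
* Minor-allele recall depends sharply on depth × fraction against the
  3-read/both-strand floor (about half of 5%-fraction minors are invisible
  at 50× even without error); recovered minor rates are therefore
  detection-model-adjusted in the tests, and real-data minor fractions
  should be compared only between samples of similar depth.
* Slipped-read realignment, duplicate marking and local realignment are
  upstream concerns; the caller consumes alignments as given.
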