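# smvtools

Somatic microsatellite variation (SMV) from tumor-only sequencing.

Microsatellites — tandem repeats of 1–6 nt motifs — are mutational
hot-spots that slip by whole repeat units far more often than surrounding
DNA acquires point mutations. In a sequenced cell population, subclonal
slippage shows up as low-frequency alleles that do not belong to the
sample's genotype. `smvtools` measures this signal exome- or genome-wide
from a single aligned sample, with no matched normal, for anyone studying
genome instability, DNA-repair deficiency signatures, or microsatellite
instability beyond small marker panels.

The package implements the full analysis stack:

* **catalogue** — detect tandem-repeat loci in a reference (built-in
  seed-and-extend detector), filter them (≥ 8 nt, ≥ 3 motif copies,
  ≥ 85% purity, non-overlapping), and sample matched non-repeat control
  segments.
* **caller** — at each locus, keep reads that fully span the repeat plus
  fixed flank anchors, pass base-quality (≥ 28 inside the repeat) and
  mapping-quality (≥ 10) filters, and match both anchors; bin identical
  allele sequences with strand-aware support. An allele is called with
  ≥ 3 supporting reads on both strands (2 and 4 also supported); loci
  with < 15 retained reads stay ungenotyped. The second most common
  allele joins the genotype when its support exceeds 25% of the binned
  reads at the locus or 50% of the major allele's support; every other
  called allele is a **minor allele**.
* **classify** — each minor allele versus the major allele: SNP (same
  length), expansion or contraction, flagged *in-phase* when the length
  change is a whole multiple of the motif (the slippage signature).
* **profile** — sample summaries (homozygous / heterozygous /
  multi-allele percentages), depth-by-allele-count tables, per-chromosome
  and 1-Mb-bin minor fractions with chi-square hotspot flags, pairwise
  concordance with an analytic and Monte-Carlo random-overlap null,
  between-sample regression, second-allele read fractions, and
  exon/untranslated and gene-level reports.
* **simulator** — synthetic references with planted diploid repeat
  genotypes and subclonal minor alleles, 2×100 bp paired-end reads with
  configurable per-base error (substitution/indel mix) and overdispersed
  or uniform coverage, emitted as in-memory records, SAM and FASTQ, plus
  evaluation of caller output against the planted truth.

## Worked example

Simulate an exome-like sample (300 loci, mean spanning depth 50, 1%
per-base error, 5% heterozygous loci, 5% of loci carrying a planted
subclonal allele), call it, and profile it:

```r
library(smvtools)

cfg  <- simulation_config(n_loci = 300L, per_base_error = 0.01,
                          het_fraction = 0.05, minor_planting_rate = 0.05,
                          seed = 7L)
sim   <- simulate_sample(cfg)
calls <- call_sample(sim$alignments, sim$catalogue, sim$reference,
                     caller_config(), verbose = TRUE)
#> called 300/300 loci (genotyped 299, with minor alleles 13)

sample_summary(calls)
#> SMV summary over 299 genotyped loci
#>   homozygous:    93.3%
#>   heterozygous:   6.7%
#>   multi-allele:   4.3%

variant_spectrum(calls, sim$catalogue)[c("n_alleles", "pct_snp",
                                         "pct_expansion", "pct_contraction")]
#> 13 minor alleles: SNP 23.1% / expansion 38.5% / contraction 38.5%

evaluate_against_truth(calls, sim$truth)
#> Simulation evaluation
#>   loci called:          300 (genotyped 299)
#>   zygosity accuracy:    100.0000%
#>   false-allele-free:    98.33% of genotyped loci
#>   planted-minor recall: 72.73%
```

Reading the numbers: 6.7% of genotyped loci were called heterozygous
(5% were planted — the remainder is binomial sampling at 300 loci), 4.3%
carry at least one minor allele (planted subclones plus a ~1.5% burden of
error-derived alleles at this error rate), every zygosity call matched the
planted truth, and 98.3% of genotyped loci contain no false allele.
Planted minors at 5–15% read fraction are recovered 73% of the time at
50× — the 3-read/both-strand floor makes low-fraction minors at moderate
depth intrinsically hard to see.

On real data the entry points are the same: `build_catalogue()` on a
reference FASTA, `call_sample()` on a coordinate-sorted BAM/SAM plus the
catalogue, then the `classify`/`profile` functions (or the thin CLI in
`inst/cli/smvtools` with subcommands `catalogue`, `simulate`, `call`,
`classify`, `profile`, `compare`).

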