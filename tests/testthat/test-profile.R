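test_that("sample summary percentages match hand counts and sum to 100", {
  calls <- fixture_calls(sprintf("L%d", 1:20),
                         c(rep("homozygous", 19L), "heterozygous"),
                         n_minor = c(1L, rep(0L, 19L)))
  s <- sample_summary(calls)
  expect_equal(s$n_genotyped, 20L)
  expect_equal(s$pct_homozygous, 95)
  expect_equal(s$pct_heterozygous, 5)
  expect_equal(s$pct_multi_allele, 5)
  expect_equal(s$pct_homozygous + s$pct_heterozygous, 100)
  # all homozygous, no minors
  s2 <- sample_summary(fixture_calls(c("a", "b"), rep("homozygous", 2L),
                                     n_minor = c(0L, 0L)))
  expect_equal(c(s2$pct_homozygous, s2$pct_heterozygous, s2$pct_multi_allele),
               c(100, 0, 0))
  # uncalled loci are excluded; nothing genotyped is an error
  un <- fixture_calls("x", "uncalled", 0L)
  expect_error(sample_summary(un), "genotyped")
})

test_that("depth-by-allele-count means match hand computation", {
  calls <- fixture_calls(sprintf("L%d", 1:6), rep("homozygous", 6L),
                         n_minor = c(0L, 0L, 1L, 1L, 2L, 0L),
                         depth = c(40L, 60L, 30L, 50L, 90L, 50L))
  tab <- depth_by_allele_count(calls)
  expect_equal(tab$n_alleles, c(1L, 2L, 3L))
  expect_equal(tab$n_loci, c(3L, 2L, 1L))
  expect_equal(tab$mean_depth, c(50, 40, 90))
})

test_that("binning assigns loci like brute-force coordinate division", {
  set.seed(50)
  n <- 200L
  catalogue <- data.frame(chrom = sample(c("c1", "c2"), n, replace = TRUE),
                          start = sample.int(5e6L, n) - 1L,
                          motif = "A", copies = 10, purity = 1,
                          stringsAsFactors = FALSE)
  catalogue$end <- catalogue$start + 10L
  catalogue$ref_length <- 10L
  catalogue$locus_id <- sprintf("B%d", seq_len(n))
  calls <- fixture_calls(catalogue$locus_id, rep("homozygous", n),
                         n_minor = rbinom(n, 1L, 0.1))
  res <- bin_minor_fractions(calls, catalogue, bin_size = 1e6)
  # conservation
  expect_equal(sum(res$bins$n_loci), n)
  expect_equal(sum(res$bins$n_minor_loci), sum(calls$calls$n_minor >= 1L))
  # brute-force re-assignment
  for (k in seq_len(nrow(res$bins))) {
    b <- res$bins[k, ]
    in_bin <- catalogue$chrom == b$chrom &
      catalogue$start >= b$bin_start & catalogue$start < b$bin_start + 1e6
    expect_equal(b$n_loci, sum(in_bin))
    expect_equal(b$fraction, mean(calls$calls$n_minor[in_bin] >= 1L))
  }
  # per-chromosome fractions agree with direct tallies
  for (ch in c("c1", "c2")) {
    sel <- catalogue$chrom == ch
    expect_equal(res$chromosomes$fraction[res$chromosomes$chrom == ch],
                 mean(calls$calls$n_minor[sel] >= 1L))
  }
})

test_that("hotspot flags follow the one-cell chi-square tail", {
  bins <- data.frame(chrom = "c", bin_start = (0:9) * 1e6,
                     n_loci = rep(200L, 10L),
                     n_minor_loci = rep(10L, 10L))
  bins$fraction <- bins$n_minor_loci / bins$n_loci
  # all at the genome-wide rate: nothing flagged
  h0 <- hotspot_bins(bins)
  expect_false(any(h0$hotspot_flag))
  # a 10x excess bin is flagged, and the statistic matches direct evaluation
  bins2 <- bins
  bins2$n_minor_loci[3L] <- 100L
  bins2$fraction <- bins2$n_minor_loci / bins2$n_loci
  h2 <- hotspot_bins(bins2, alpha = 0.01)
  expect_true(h2$hotspot_flag[3L])
  rate <- sum(bins2$n_minor_loci) / sum(bins2$n_loci)
  ex3 <- rate * 200L
  expect_equal(h2$chi_square[3L], (100L - ex3)^2 / ex3)
  expect_equal(h2$p_value[3L], pchisq((100L - ex3)^2 / ex3, 1,
                                      lower.tail = FALSE))
  # a symmetric deficit is never flagged (upper tail only)
  bins3 <- bins
  bins3$n_minor_loci[5L] <- 0L
  h3 <- hotspot_bins(bins3, alpha = 0.05)
  expect_false(h3$hotspot_flag[5L])
  # flags are invariant under row order
  sh <- sample(nrow(bins2))
  h2s <- hotspot_bins(bins2[sh, ], alpha = 0.01)
  expect_equal(h2s$hotspot_flag[order(sh)], h2$hotspot_flag)
  # zero-locus bins are skipped
  bins4 <- bins
  bins4$n_loci[1L] <- 0L
  bins4$n_minor_loci[1L] <- 0L
  expect_false(hotspot_bins(bins4)$hotspot_flag[1L])
})

test_that("concordance categories match the 10-locus worked example", {
  hap <- replicate(10L, list("AAAA"))
  minors_a <- seq_len(10L) %in% c(1L, 2L, 3L)
  minors_b <- seq_len(10L) %in% c(2L, 3L, 4L)
  px <- fixture_pair_calls(hap, hap, minors_a, minors_b)
  cc <- compare_samples(px$a, px$b)
  expect_equal(cc$n_shared_loci, 10L)
  expect_equal(cc$pct_genotype_discordance, 0)
  expect_equal(cc$pct_minor_concordant, 20)
  expect_equal(cc$pct_minor_discordant, 20)
  expect_equal(cc$pct_no_minor_concordant, 60)
  expect_equal(cc$pct_minor_concordant + cc$pct_minor_discordant +
                 cc$pct_no_minor_concordant, 100)
  # identical call sets: no discordance of any kind
  cc2 <- compare_samples(px$a, px$a)
  expect_equal(cc2$pct_genotype_discordance, 0)
  expect_equal(cc2$pct_minor_discordant, 0)
})

test_that("genotype discordance splits threshold-boundary vs sequence cases", {
  # locus S1: A is het (AAAA/AATA), B called homozygous but observed AATA as
  # a minor -> threshold-boundary discordance. locus S2: different haplotype
  # sequences entirely -> sequence discordance. S3: concordant.
  hap_a <- list(c("AAAA", "AATA"), "CCCC", "GGGG")
  hap_b <- list("AAAA", "CGCC", "GGGG")
  px <- fixture_pair_calls(hap_a, hap_b, rep(FALSE, 3L), rep(FALSE, 3L))
  # add AATA as a minor allele of S1 in sample b
  extra <- data.frame(allele_seq = "AATA", length = 4L, n_forward = 2L,
                      n_reverse = 2L, n_total = 4L, role = "minor",
                      rank = 2L, locus_id = "S1", stringsAsFactors = FALSE)
  px$b$alleles <- rbind(px$b$alleles, extra)
  px$b$calls$n_minor[px$b$calls$locus_id == "S1"] <- 1L
  cc <- compare_samples(px$a, px$b)
  expect_equal(cc$pct_genotype_discordance, 100 * 2 / 3)
  expect_equal(cc$pct_discordance_threshold, 50)
  expect_equal(cc$pct_discordance_sequence, 50)
  expect_equal(cc$n_discordant_sequence, 1L)
})

test_that("concordance null matches the product formula and Monte Carlo", {
  # paper-style fractions: 5.4% and 5.3% give 0.2862% expected overlap
  nn <- concordance_null(280000L, 0.054, 0.053, observed_concordant = 9600L,
                         n_reps = 0L)
  expect_equal(nn$expected_pct, 0.2862, tolerance = 1e-12)
  # degenerate case
  n0 <- concordance_null(100L, 0, 0, 0L, n_reps = 0L)
  expect_equal(n0$expected_pct, 0)
  expect_equal(n0$p_value, 1)
  # Monte-Carlo mean close to the analytic expectation
  mc <- concordance_null(2000L, 0.2, 0.1, 40L, n_reps = 1000L, seed = 5L)
  se <- mc$mc_sd_fraction / sqrt(1000L)
  expect_lt(abs(mc$mc_mean_fraction - 0.02), 3 * se + 1e-9)
  # the chi-square test detects a strong excess
  expect_lt(concordance_null(10000L, 0.05, 0.05, 340L,
                             n_reps = 0L)$p_value, 1e-4)
  expect_error(concordance_null(0L, 0.1, 0.1, 0L), "positive")
})

test_that("between-sample regression matches closed-form least squares", {
  # exact line (lm warns about the perfect fit; the numbers are exact)
  r1 <- suppressWarnings(between_sample_regression(1:10, 1:10))
  expect_equal(r1$r_squared, 1)
  expect_equal(r1$slope, 1)
  expect_equal(r1$intercept, 0)
  # hand-computed five-point set
  x <- c(1, 2, 3, 4, 5)
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  r2 <- between_sample_regression(x, y)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  b <- sxy / sxx
  a <- mean(y) - b * mean(x)
  r2_closed <- sxy^2 / (sxx * sum((y - mean(y))^2))
  expect_equal(r2$slope, b)
  expect_equal(r2$intercept, a)
  expect_equal(r2$r_squared, r2_closed)
  # identical permutation of both vectors leaves R^2 unchanged
  perm <- c(3L, 1L, 5L, 2L, 4L)
  r3 <- between_sample_regression(x[perm], y[perm])
  expect_equal(r3$r_squared, r2$r_squared)
  expect_error(between_sample_regression(rep(1, 5), 1:5), "variance")
})

test_that("second-allele read fractions average the scoped loci only", {
  ids <- c("L1", "L2", "L3")
  calls <- fixture_calls(ids, c("homozygous", "heterozygous", "homozygous"),
                         n_minor = c(1L, 1L, 0L),
                         depth = c(100L, 80L, 60L))
  al <- rbind(
    data.frame(allele_seq = "AAAA", length = 4L, n_forward = 46L,
               n_reverse = 46L, n_total = 92L, role = "haplotype1",
               rank = 1L, locus_id = "L1", stringsAsFactors = FALSE),
    data.frame(allele_seq = "AAA", length = 3L, n_forward = 4L,
               n_reverse = 4L, n_total = 8L, role = "minor",
               rank = 2L, locus_id = "L1", stringsAsFactors = FALSE),
    data.frame(allele_seq = "CCCC", length = 4L, n_forward = 20L,
               n_reverse = 20L, n_total = 40L, role = "haplotype1",
               rank = 1L, locus_id = "L2", stringsAsFactors = FALSE),
    data.frame(allele_seq = "CCCCCC", length = 6L, n_forward = 15L,
               n_reverse = 15L, n_total = 30L, role = "haplotype2",
               rank = 2L, locus_id = "L2", stringsAsFactors = FALSE),
    data.frame(allele_seq = "CC", length = 2L, n_forward = 2L,
               n_reverse = 2L, n_total = 4L, role = "minor",
               rank = 3L, locus_id = "L2", stringsAsFactors = FALSE))
  calls$alleles <- al
  fr <- second_allele_read_fractions(calls)
  expect_equal(fr$n_loci, 2L)
  # minor fractions: 8/100 and 4/80
  expect_equal(fr$mean_minor_fraction, mean(c(0.08, 0.05)))
  # second alleles: rank 2 support 8/100 and 30/80
  expect_equal(fr$mean_second_allele_fraction, mean(c(0.08, 0.375)))
  # no qualifying loci -> flagged empty
  none <- fixture_calls("x", "homozygous", 0L)
  expect_true(second_allele_read_fractions(none)$empty)
})

test_that("exon partition and gene report follow any-overlap assignment", {
  catalogue <- data.frame(chrom = "c1", start = c(100L, 300L, 500L, 700L),
                          end = c(120L, 320L, 520L, 720L),
                          motif = "A", copies = 20, purity = 1,
                          ref_length = 20L,
                          locus_id = sprintf("G%d", 1:4),
                          stringsAsFactors = FALSE)
  exons <- data.frame(chrom = "c1",
                      start = c(90L, 515L, 695L),
                      end = c(110L, 530L, 730L),
                      gene = c("GENE1", "GENE2", "GENE3"),
                      stringsAsFactors = FALSE)
  calls <- fixture_calls(sprintf("G%d", 1:4),
                         c("homozygous", "homozygous", "homozygous",
                           "heterozygous"),
                         n_minor = c(2L, 1L, 0L, 2L))
  res <- region_partition_summary(calls, catalogue, exons)
  # locus G1 overlaps GENE1 partially -> exonic; G2 overlaps nothing
  expect_equal(res$exonic$n_genotyped, 3L)
  expect_equal(res$untranslated$n_genotyped, 1L)
  # gene report: loci with >= 2 minors are G1 (GENE1) and G4 (GENE3)
  expect_setequal(res$gene_report$gene, c("GENE1", "GENE3"))
  # multi-sample presence counts
  calls2 <- fixture_calls(sprintf("G%d", 1:4), rep("homozygous", 4L),
                          n_minor = c(2L, 0L, 0L, 0L))
  res2 <- region_partition_summary(list(s1 = calls, s2 = calls2),
                                   catalogue, exons)
  expect_equal(res2$gene_report$n_samples[res2$gene_report$gene == "GENE1"], 2L)
  expect_equal(res2$gene_report$n_samples[res2$gene_report$gene == "GENE3"], 1L)
  # empty annotation degrades to untranslated-only with a warning
  expect_warning(res3 <- region_partition_summary(calls, catalogue,
                                                  exons[0L, ]), "empty")
  expect_null(res3$exonic)
})

test_that("profile recovers simulator parameters within sampling error", {
  cfg <- simulation_config(n_loci = 600L, per_base_error = 0,
                           het_fraction = 0.06, minor_planting_rate = 0.1,
                           seed = 71L)
  sim <- simulate_sample(cfg)
  res <- call_sample(sim$alignments, sim$catalogue, sim$reference,
                     caller_config())
  s <- sample_summary(res)
  truth_het <- sum(sim$truth$zygosity_truth == "heterozygous")
  ci <- qbinom(c(0.005, 0.995), 600L, 0.06)
  expect_gte(truth_het, ci[1L])
  expect_lte(truth_het, ci[2L])
  # called het percent within the binomial envelope of the planted rate
  expect_gte(s$pct_heterozygous, 100 * (ci[1L] - 2L) / s$n_genotyped)
  expect_lte(s$pct_heterozygous, 100 * (ci[2L] + 2L) / s$n_genotyped)
})
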