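# Sample-level somatic microsatellite variation (SMV) statistics: zygosity
# and minor-allele summaries, depth tables, genomic binning with chi-square
# hotspot flags, pairwise concordance with a randomization null, regression
# between samples, read-fraction summaries, and exon/gene partitions.

.genotyped <- function(calls_df) {
  calls_df[calls_df$zygosity %in% c("homozygous", "heterozygous"), ,
           drop = FALSE]
}

#' Sample-level SMV summary
#'
#' Percent homozygous and heterozygous loci (summing to 100 over genotyped
#' loci) and percent of genotyped loci carrying at least one minor allele.
#'
#' @param calls An `smv_calls` object (or its `calls` data frame).
#' @param spectrum Optional variant spectrum (see [variant_spectrum()])
#'   carried along in the result.
#' @return List of class `smv_summary`.
#' @export
sample_summary <- function(calls, spectrum = NULL) {
  cl <- if (inherits(calls, "smv_calls")) calls$calls else calls
  g <- .genotyped(cl)
  if (nrow(g) == 0L) stop("no genotyped loci to summarize", call. = FALSE)
  structure(list(n_genotyped = nrow(g),
                 pct_homozygous = 100 * mean(g$zygosity == "homozygous"),
                 pct_heterozygous = 100 * mean(g$zygosity == "heterozygous"),
                 pct_multi_allele = 100 * mean(g$n_minor >= 1L),
                 spectrum = spectrum),
            class = "smv_summary")
}

#' @export
print.smv_summary <- function(x, ...) {
  cat(sprintf("SMV summary over %d genotyped loci\n", x$n_genotyped))
  cat(sprintf("  homozygous:   %5.1f%%\n", x$pct_homozygous))
  cat(sprintf("  heterozygous: %5.1f%%\n", x$pct_heterozygous))
  cat(sprintf("  multi-allele: %5.1f%%\n", x$pct_multi_allele))
  invisible(x)
}

#' Mean locus depth by called allele count
#'
#' @param calls An `smv_calls` object or its `calls` data frame.
#' @return Data frame `n_alleles`, `n_loci`, `mean_depth`.
#' @export
depth_by_allele_count <- function(calls) {
  cl <- if (inherits(calls, "smv_calls")) calls$calls else calls
  g <- .genotyped(cl)
  if (nrow(g) == 0L) {
    return(data.frame(n_alleles = integer(0), n_loci = integer(0),
                      mean_depth = numeric(0)))
  }
  agg <- aggregate(g$depth, by = list(n_alleles = g$n_alleles_total),
                   FUN = function(v) c(n = length(v), mean = mean(v)))
  data.frame(n_alleles = agg$n_alleles,
             n_loci = as.integer(agg$x[, "n"]),
             mean_depth = agg$x[, "mean"])
}

#' Fraction of minor-allele loci per genomic bin and per chromosome
#'
#' Assigns every genotyped locus (by its start coordinate) to one fixed-size
#' bin and reports the fraction of loci with at least one minor allele per
#' bin and per chromosome.
#'
#' @param calls An `smv_calls` object.
#' @param catalogue Catalogue data frame (coordinates per locus_id).
#' @param bin_size Bin width in nucleotides (default 1 Mb).
#' @return List with `bins` (chrom, bin_start, n_loci, n_minor_loci,
#'   fraction) and `chromosomes` (per-chromosome fractions).
#' @export
bin_minor_fractions <- function(calls, catalogue, bin_size = 1e6) {
  cl <- if (inherits(calls, "smv_calls")) calls$calls else calls
  g <- .genotyped(cl)
  ci <- match(g$locus_id, catalogue$locus_id)
  chrom <- catalogue$chrom[ci]
  bin_start <- (catalogue$start[ci] %/% bin_size) * bin_size
  key <- paste(chrom, bin_start)
  n_loci <- tapply(rep(1L, nrow(g)), key, sum)
  n_minor <- tapply(g$n_minor >= 1L, key, sum)
  ord <- names(n_loci)
  parts <- strsplit(ord, " ", fixed = TRUE)
  bins <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                     bin_start = as.numeric(vapply(parts, `[`, "", 2L)),
                     n_loci = as.integer(n_loci),
                     n_minor_loci = as.integer(n_minor),
                     stringsAsFactors = FALSE)
  bins$fraction <- bins$n_minor_loci / bins$n_loci
  bins <- bins[order(bins$chrom, bins$bin_start), , drop = FALSE]
  rownames(bins) <- NULL
  nc <- tapply(rep(1L, nrow(g)), chrom, sum)
  mc <- tapply(g$n_minor >= 1L, chrom, sum)
  chromosomes <- data.frame(chrom = names(nc),
                            n_loci = as.integer(nc),
                            n_minor_loci = as.integer(mc),
                            stringsAsFactors = FALSE)
  chromosomes$fraction <- chromosomes$n_minor_loci / chromosomes$n_loci
  rownames(chromosomes) <- NULL
  list(bins = bins, chromosomes = chromosomes)
}

#' Flag hotspot bins by a chi-square goodness-of-fit excess
#'
#' Each bin's observed minor-allele locus count is compared with the
#' genome-wide rate times the bin's locus count using a one-cell 1-df
#' goodness-of-fit statistic, upper tail; a bin is flagged when its count
#' exceeds expectation with p below `alpha`. No multiple-testing correction
#' is applied by default; `bonferroni = TRUE` divides `alpha` by the number
#' of testable bins.
#'
#' @param bins `bins` data frame from [bin_minor_fractions()].
#' @param alpha Significance level (default 0.01).
#' @param bonferroni Apply a Bonferroni correction (default FALSE).
#' @return The bins data frame with `expected`, `chi_square`, `p_value` and
#'   `hotspot_flag` columns; bins with zero loci are skipped (flag FALSE).
#' @export
hotspot_bins <- function(bins, alpha = 0.01, bonferroni = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  b <- bins
  usable <- b$n_loci > 0L
  rate <- sum(b$n_minor_loci[usable]) / sum(b$n_loci[usable])
  b$expected <- rate * b$n_loci
  b$chi_square <- NA_real_
  b$p_value <- NA_real_
  ok <- usable & b$expected > 0
  b$chi_square[ok] <- (b$n_minor_loci[ok] - b$expected[ok])^2 / b$expected[ok]
  b$p_value[ok] <- stats::pchisq(b$chi_square[ok], df = 1L,
                                 lower.tail = FALSE)
  thr <- if (bonferroni) alpha / sum(ok) else alpha
  b$hotspot_flag <- !is.na(b$p_value) & b$p_value < thr &
    b$n_minor_loci > b$expected
  b
}

# Haplotype allele-sequence key per locus, for genotype comparison.
.hap_keys <- function(calls) {
  al <- calls$alleles
  hap <- al[al$role %in% c("haplotype1", "haplotype2"), , drop = FALSE]
  keys <- tapply(hap$allele_seq, hap$locus_id,
                 function(s) paste(sort(s), collapse = "|"))
  keys
}

#' Pairwise sample concordance
#'
#' Compares two call sets over the loci genotyped in both. Reports the
#' percent of shared loci with discordant genotypes (haplotype allele
#' sets), split into threshold-boundary discordance (the same allele
#' sequences were observed in both samples, only the heterozygote-threshold
#' classification differs) and true sequence differences; and the
#' minor-allele categories: concordant (minor alleles in both), discordant
#' (minor alleles in exactly one) and no-minor concordant (in neither),
#' which sum to 100. A Pearson goodness-of-fit test against the
#' random-overlap expectation is included.
#'
#' @param calls_a,calls_b `smv_calls` objects.
#' @return List of class `smv_concordance`.
#' @export
compare_samples <- function(calls_a, calls_b) {
  ga <- .genotyped(calls_a$calls)
  gb <- .genotyped(calls_b$calls)
  shared <- intersect(ga$locus_id, gb$locus_id)
  n <- length(shared)
  if (n == 0L) stop("no loci genotyped in both samples", call. = FALSE)
  ia <- match(shared, ga$locus_id)
  ib <- match(shared, gb$locus_id)
  keys_a <- .hap_keys(calls_a)
  keys_b <- .hap_keys(calls_b)
  ka <- keys_a[shared]
  kb <- keys_b[shared]
  disc <- ka != kb
  # threshold-boundary discordance: each sample's haplotype alleles all
  # appear among the other sample's called alleles
  called_seqs <- function(calls) {
    tapply(calls$alleles$allele_seq, calls$alleles$locus_id,
           function(s) s, simplify = FALSE)
  }
  ca <- called_seqs(calls_a)
  cb <- called_seqs(calls_b)
  thr <- vapply(shared, function(lid) {
    ha <- strsplit(keys_a[[lid]], "|", fixed = TRUE)[[1L]]
    hb <- strsplit(keys_b[[lid]], "|", fixed = TRUE)[[1L]]
    all(ha %in% cb[[lid]]) && all(hb %in% ca[[lid]])
  }, logical(1L))
  n_disc <- sum(disc)
  n_disc_threshold <- sum(disc & thr)
  n_disc_sequence <- sum(disc & !thr)
  ma <- ga$n_minor[ia] >= 1L
  mb <- gb$n_minor[ib] >= 1L
  n_minor_conc <- sum(ma & mb)
  n_minor_disc <- sum(xor(ma, mb))
  n_no_minor <- sum(!ma & !mb)
  null <- concordance_null(n, mean(ma), mean(mb), n_minor_conc,
                           n_reps = 0L, seed = 1L)
  structure(list(n_shared_loci = n,
                 pct_genotype_discordance = 100 * n_disc / n,
                 pct_discordance_threshold = if (n_disc) 100 * n_disc_threshold / n_disc else NA_real_,
                 pct_discordance_sequence = if (n_disc) 100 * n_disc_sequence / n_disc else NA_real_,
                 n_discordant_sequence = n_disc_sequence,
                 pct_minor_concordant = 100 * n_minor_conc / n,
                 pct_minor_discordant = 100 * n_minor_disc / n,
                 pct_no_minor_concordant = 100 * n_no_minor / n,
                 expected_concordant_pct = null$expected_pct,
                 chi_square_stat = null$chi_square_stat,
                 p_value = null$p_value),
            class = "smv_concordance")
}

#' @export
print.smv_concordance <- function(x, ...) {
  cat(sprintf("Concordance over %d shared loci\n", x$n_shared_loci))
  cat(sprintf("  genotype discordance: %.2f%%\n", x$pct_genotype_discordance))
  cat(sprintf("  minor concordant / discordant / neither: %.2f%% / %.2f%% / %.2f%%\n",
              x$pct_minor_concordant, x$pct_minor_discordant,
              x$pct_no_minor_concordant))
  cat(sprintf("  random expectation %.4f%%, X^2 = %.1f, p = %.3g\n",
              x$expected_concordant_pct, x$chi_square_stat, x$p_value))
  invisible(x)
}

#' Random-overlap null for minor-allele concordance
#'
#' Under random placement, the expected fraction of shared loci with minor
#' alleles in both samples is the product of the per-sample fractions. A
#' Pearson 1-df goodness-of-fit test compares the observed concordant count
#' with this expectation, and an optional Monte-Carlo null re-draws random
#' subsets of the appropriate sizes.
#'
#' @param n_shared Number of shared loci.
#' @param frac_a,frac_b Fractions of loci with minor alleles in each sample.
#' @param observed_concordant Observed count of loci with minors in both.
#' @param n_reps Monte-Carlo replicates (0 to skip; default 1000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return List with `expected_fraction`, `expected_pct`,
#'   `chi_square_stat`, `p_value`, and (when `n_reps > 0`) `mc_mean_fraction`
#'   and `mc_sd_fraction`.
#' @export
concordance_null <- function(n_shared, frac_a, frac_b, observed_concordant,
                             n_reps = 1000L, seed = 1L) {
  stopifnot(frac_a >= 0, frac_a <= 1, frac_b >= 0, frac_b <= 1)
  if (n_shared == 0L) stop("n_shared must be positive", call. = FALSE)
  expected_fraction <- frac_a * frac_b
  E <- expected_fraction * n_shared
  O <- observed_concordant
  if (E > 0 && E < n_shared) {
    stat <- (O - E)^2 / E + ((n_shared - O) - (n_shared - E))^2 / (n_shared - E)
    p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)
  } else {
    stat <- if (O == E) 0 else Inf
    p <- if (O == E) 1 else 0
  }
  out <- list(expected_fraction = expected_fraction,
              expected_pct = 100 * expected_fraction,
              chi_square_stat = stat, p_value = p)
  if (n_reps > 0L) {
    set.seed(seed)
    na <- round(frac_a * n_shared)
    nb <- round(frac_b * n_shared)
    draws <- vapply(seq_len(n_reps), function(i) {
      a <- sample.int(n_shared, na)
      b <- sample.int(n_shared, nb)
      length(intersect(a, b)) / n_shared
    }, numeric(1L))
    out$mc_mean_fraction <- mean(draws)
    out$mc_sd_fraction <- stats::sd(draws)
  }
  out
}

#' Ordinary least-squares comparison of paired fractions
#'
#' Regresses one sample's per-chromosome (or per-bin) minor-allele fractions
#' on another's, preserving the input pairing.
#'
#' @param fractions_a Predictor vector.
#' @param fractions_b Response vector, same length (>= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value` (F test),
#'   `n`.
#' @export
between_sample_regression <- function(fractions_a, fractions_b) {
  stopifnot(length(fractions_a) == length(fractions_b),
            length(fractions_a) >= 3L)
  if (stats::var(fractions_a) == 0) {
    stop("predictor has zero variance", call. = FALSE)
  }
  fit <- stats::lm(fractions_b ~ fractions_a)
  sm <- summary(fit)
  p <- if (is.null(sm$fstatistic)) NA_real_ else
    stats::pf(sm$fstatistic[1L], sm$fstatistic[2L], sm$fstatistic[3L],
              lower.tail = FALSE)
  list(slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = unname(sm$r.squared),
       p_value = unname(p),
       n = length(fractions_a))
}

#' Mean read fractions supporting minor and second alleles
#'
#' Over loci with at least one minor allele: the mean per-locus fraction of
#' reads supporting minor alleles, and the mean fraction supporting the
#' second allele (the second haplotype allele at heterozygous loci, the top
#' minor allele at homozygous ones).
#'
#' @param calls An `smv_calls` object.
#' @return List with `mean_minor_fraction`, `mean_second_allele_fraction`,
#'   `n_loci`; with no qualifying loci, fractions are NA and `empty` TRUE.
#' @export
second_allele_read_fractions <- function(calls) {
  cl <- .genotyped(calls$calls)
  sel <- cl[cl$n_minor >= 1L, , drop = FALSE]
  if (nrow(sel) == 0L) {
    return(list(mean_minor_fraction = NA_real_,
                mean_second_allele_fraction = NA_real_,
                n_loci = 0L, empty = TRUE))
  }
  al <- calls$alleles[calls$alleles$locus_id %in% sel$locus_id, , drop = FALSE]
  minor_sum <- tapply(al$n_total * (al$role == "minor"), al$locus_id, sum)
  second <- tapply(al$n_total * (al$rank == 2L), al$locus_id, sum)
  depth <- sel$depth[match(names(minor_sum), sel$locus_id)]
  minor_frac <- as.numeric(minor_sum) / depth
  depth2 <- sel$depth[match(names(second), sel$locus_id)]
  second_frac <- as.numeric(second) / depth2
  list(mean_minor_fraction = mean(minor_frac),
       mean_second_allele_fraction = mean(second_frac),
       n_loci = nrow(sel), empty = FALSE)
}

#' Exon vs untranslated partition and gene-level report
#'
#' A locus is exonic iff it overlaps any exon interval (>= 1 bp). Summaries
#' are computed per partition, and the gene report lists genes with at least
#' one exonic locus carrying two or more minor alleles; when several call
#' sets are supplied, per-sample presence counts are added.
#'
#' @param calls An `smv_calls` object, or a named list of them for
#'   multi-sample gene reports.
#' @param catalogue Catalogue data frame.
#' @param exon_annotation Data frame with `chrom`, `start`, `end` (0-based
#'   half-open, BED-style) and `gene` columns.
#' @param min_minor_alleles Minor alleles required at a locus for the gene
#'   report (default 2).
#' @return List with `exonic` and `untranslated` summaries (see
#'   [sample_summary()]) for the first sample, and `gene_report`.
#' @export
region_partition_summary <- function(calls, catalogue, exon_annotation,
                                     min_minor_alleles = 2L) {
  multi <- !inherits(calls, "smv_calls")
  call_list <- if (multi) calls else list(sample = calls)
  if (is.null(exon_annotation) || nrow(exon_annotation) == 0L) {
    warning("empty exon annotation; reporting untranslated-only summary")
    s <- sample_summary(call_list[[1L]])
    return(list(exonic = NULL, untranslated = s,
                gene_report = data.frame(gene = character(0),
                                         n_samples = integer(0))))
  }
  ex_gr <- GenomicRanges::GRanges(
    exon_annotation$chrom,
    IRanges::IRanges(exon_annotation$start + 1L, exon_annotation$end))
  cat_gr <- GenomicRanges::GRanges(
    catalogue$chrom, IRanges::IRanges(catalogue$start + 1L, catalogue$end))
  hits <- GenomicRanges::findOverlaps(cat_gr, ex_gr)
  exonic_ids <- unique(catalogue$locus_id[S4Vectors::queryHits(hits)])
  # locus -> genes map
  l2g <- unique(data.frame(
    locus_id = catalogue$locus_id[S4Vectors::queryHits(hits)],
    gene = exon_annotation$gene[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE))
  part_summary <- function(cl, ids, inside) {
    sub <- cl$calls[xor(!inside, cl$calls$locus_id %in% ids), , drop = FALSE]
    if (nrow(.genotyped(sub)) == 0L) return(NULL)
    sample_summary(sub)
  }
  first <- call_list[[1L]]
  exonic <- part_summary(first, exonic_ids, TRUE)
  untranslated <- part_summary(first, exonic_ids, FALSE)
  # gene report across samples
  per_sample_genes <- lapply(call_list, function(cs) {
    g <- .genotyped(cs$calls)
    qual <- g$locus_id[g$n_minor >= min_minor_alleles]
    unique(l2g$gene[l2g$locus_id %in% qual])
  })
  genes <- sort(unique(unlist(per_sample_genes)))
  if (length(genes)) {
    pres <- vapply(genes, function(gn) {
      sum(vapply(per_sample_genes, function(v) gn %in% v, logical(1L)))
    }, integer(1L))
    gene_report <- data.frame(gene = genes, n_samples = pres,
                              stringsAsFactors = FALSE)
    rownames(gene_report) <- NULL
  } else {
    gene_report <- data.frame(gene = character(0), n_samples = integer(0))
  }
  list(exonic = exonic, untranslated = untranslated,
       gene_report = gene_report)
}
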