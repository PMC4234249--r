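# Minor-allele caller: extract repeat-spanning reads at each catalogued
# locus, tally distinct allele sequences with strand-aware support, and call
# haplotype and minor alleles.

#' Caller configuration
#'
#' @param flank_length Length of the flank anchors delimiting the repeat in
#'   a read (5 or 7 in typical use; default 5).
#' @param min_base_quality Minimum Phred base quality inside the repeat
#'   (default 28); a read with any repeat base below this is dropped.
#' @param min_mapping_quality Minimum mapping quality (default 10).
#' @param min_reads_per_allele Minimum supporting reads for an allele call
#'   (default 3; 2 and 4 are the other studied settings).
#' @param min_locus_depth Minimum retained read depth to genotype a locus
#'   (default 15).
#' @param het_total_fraction Second-allele support must exceed this fraction
#'   of locus depth to join the haplotype (default 0.25), or ...
#' @param het_major_fraction ... exceed this fraction of the major allele's
#'   support (default 0.50).
#' @param both_strand_required Require at least one forward and one reverse
#'   supporting read per allele (default TRUE).
#' @param allow_flank_mismatch Number of mismatches tolerated in each flank
#'   anchor (0 or 1; default 0, exact anchors).
#' @return An object of class `caller_config`.
#' @export
caller_config <- function(flank_length = 5L,
                          min_base_quality = 28L,
                          min_mapping_quality = 10L,
                          min_reads_per_allele = 3L,
                          min_locus_depth = 15L,
                          het_total_fraction = 0.25,
                          het_major_fraction = 0.50,
                          both_strand_required = TRUE,
                          allow_flank_mismatch = 0L) {
  stopifnot(flank_length >= 1L, min_base_quality >= 0L,
            min_mapping_quality >= 0L, min_reads_per_allele >= 2L,
            min_locus_depth >= 1L,
            het_total_fraction > 0, het_total_fraction < 1,
            het_major_fraction > 0, het_major_fraction <= 1,
            allow_flank_mismatch %in% c(0L, 1L))
  structure(list(flank_length = as.integer(flank_length),
                 min_base_quality = as.integer(min_base_quality),
                 min_mapping_quality = as.integer(min_mapping_quality),
                 min_reads_per_allele = as.integer(min_reads_per_allele),
                 min_locus_depth = as.integer(min_locus_depth),
                 het_total_fraction = het_total_fraction,
                 het_major_fraction = het_major_fraction,
                 both_strand_required = isTRUE(both_strand_required),
                 allow_flank_mismatch = as.integer(allow_flank_mismatch)),
            class = "caller_config")
}

.prep_alignments <- function(aln) {
  if (is.character(aln) && length(aln) == 1L) aln <- read_alignments(aln)
  if (is.null(aln$strand)) {
    aln$strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
  }
  ok <- !is.na(aln$cigar) & aln$cigar != "*" & !is.na(aln$pos)
  n_malformed <- sum(!ok)
  aln <- aln[ok, , drop = FALSE]
  aln$ref_end <- aln$pos +
    GenomicAlignments::cigarWidthAlongReferenceSpace(aln$cigar) - 1L
  attr(aln, "n_malformed") <- n_malformed
  aln
}

# All anchor match positions at or after `from`, tolerating up to `mm`
# mismatches. Returns an integer vector (possibly empty).
.match_anchor_all <- function(read, anchor, mm, from = 1L) {
  if (mm == 0L) {
    # lookahead so that overlapping occurrences (anchors ending in a
    # partial repeat of themselves) are all reported
    hits <- gregexpr(paste0("(?=", anchor, ")"), read, perl = TRUE)[[1L]]
    if (hits[1L] < 0L) return(integer(0))
    return(as.integer(hits[hits >= from]))
  }
  la <- nchar(anchor)
  av <- utf8ToInt(anchor)
  rv <- utf8ToInt(read)
  last <- length(rv) - la + 1L
  if (last < from) return(integer(0))
  out <- integer(0)
  for (s in from:last) {
    if (sum(rv[s:(s + la - 1L)] != av) <= mm) out <- c(out, s)
  }
  out
}

#' Extract repeat-spanning read observations at one locus
#'
#' Retains reads that (a) fully span the repeat plus both flank anchors,
#' (b) pass the mapping-quality filter, (c) have all base qualities inside
#' the repeat at or above `min_base_quality`, and (d) match both flank
#' anchors. The allele sequence is the read substring between the anchors,
#' so insertions or deletions inside the repeat change its length.
#'
#' @param alignments Alignment data frame (see [read_alignments()]) or a
#'   SAM/BAM path.
#' @param locus One catalogue row (data frame with `chrom`, `start`, `end`,
#'   `locus_id`).
#' @param reference Reference sequences (for the anchor sequences).
#' @param config A [caller_config()].
#' @return Data frame of observations: `locus_id`, `allele_seq`, `strand`,
#'   `read_name`.
#' @export
extract_observations <- function(alignments, locus, reference,
                                 config = caller_config()) {
  aln <- .prep_alignments(alignments)
  reference <- load_reference(reference)
  F <- config$flank_length
  sub <- aln[aln$chrom == locus$chrom &
               aln$pos <= locus$start - F + 1L &
               aln$ref_end >= locus$end + F, , drop = FALSE]
  .extract_locus_obs(seqs = sub$seq, quals = sub$qual, strands = sub$strand,
                     mapqs = sub$mapq, qnames = sub$qname, poss = sub$pos,
                     locus = locus, refseq = reference[[locus$chrom]],
                     config = config)
}

# The left anchor is located at the occurrence closest to its
# alignment-expected read offset (a random flank 5-mer recurs elsewhere in
# a 100-nt read often enough that "first occurrence" is wrong); the right
# anchor is the first occurrence after the left anchor.
.extract_locus_obs <- function(seqs, quals, strands, mapqs, qnames, poss,
                               locus, refseq, config) {
  F <- config$flank_length
  empty <- data.frame(locus_id = character(0), allele_seq = character(0),
                      strand = character(0), read_name = character(0),
                      stringsAsFactors = FALSE)
  keep <- mapqs >= config$min_mapping_quality
  if (!any(keep)) return(empty)
  seqs <- seqs[keep]; quals <- quals[keep]
  strands <- strands[keep]; qnames <- qnames[keep]; poss <- poss[keep]
  left <- substr(refseq, locus$start - F + 1L, locus$start)
  right <- substr(refseq, locus$end + 1L, locus$end + F)
  mm <- config$allow_flank_mismatch
  expected1 <- (locus$start - F + 1L) - poss + 1L
  n <- length(seqs)
  i1 <- rep(-1L, n)
  i2 <- rep(-1L, n)
  if (mm == 0L) {
    # overlapping occurrences matter when the anchor tail matches the
    # repeat head, hence the lookahead form
    hits1 <- gregexpr(paste0("(?=", left, ")"), seqs, perl = TRUE)
    for (i in seq_len(n)) {
      h <- hits1[[i]]
      if (h[1L] < 0L) next
      i1[i] <- h[which.min(abs(h - expected1[i]))]
    }
    ok <- i1 > 0L
    a_from <- i1 + F
    tail_str <- substr(seqs, a_from, nchar(seqs))
    i2rel <- as.integer(regexpr(right, tail_str, fixed = TRUE))
    found <- ok & i2rel > 0L
    i2 <- a_from - 1L + i2rel
  } else {
    for (i in seq_len(n)) {
      h <- .match_anchor_all(seqs[i], left, mm)
      if (!length(h)) next
      i1[i] <- h[which.min(abs(h - expected1[i]))]
      h2 <- .match_anchor_all(seqs[i], right, mm, from = i1[i] + F)
      if (length(h2)) i2[i] <- h2[1L]
    }
    found <- i1 > 0L & i2 > 0L
  }
  if (!any(found)) return(empty)
  a_start <- a_from[found]
  a_end <- i2[found] - 1L
  allele <- substr(seqs[found], a_start, a_end)
  # base quality over the repeat bases (an empty allele passes trivially)
  q <- quals[found]
  minq <- config$min_base_quality + 33L
  qok <- vapply(seq_along(q), function(i) {
    if (a_end[i] < a_start[i]) return(TRUE)
    all(utf8ToInt(substr(q[i], a_start[i], a_end[i])) >= minq)
  }, logical(1L))
  data.frame(locus_id = rep(locus$locus_id, sum(qok)),
             allele_seq = allele[qok],
             strand = strands[found][qok],
             read_name = qnames[found][qok],
             stringsAsFactors = FALSE)
}

#' Tally called alleles from read observations
#'
#' Groups observations by exact allele sequence; an allele is called iff its
#' total support reaches `min_reads_per_allele` and (by default) it is seen
#' on both strands. Output is sorted by support (descending), with ties
#' broken by longer allele then lexicographic sequence.
#'
#' @param observations Observation data frame from one locus.
#' @param config A [caller_config()].
#' @return Data frame of called alleles: `allele_seq`, `length`,
#'   `n_forward`, `n_reverse`, `n_total`.
#' @export
tally_alleles <- function(observations, config = caller_config()) {
  empty <- data.frame(allele_seq = character(0), length = integer(0),
                      n_forward = integer(0), n_reverse = integer(0),
                      n_total = integer(0), stringsAsFactors = FALSE)
  if (is.null(observations) || nrow(observations) == 0L) return(empty)
  alleles <- sort(unique(observations$allele_seq))
  fwd <- table(factor(observations$allele_seq[observations$strand == "+"],
                      levels = alleles))
  rev <- table(factor(observations$allele_seq[observations$strand == "-"],
                      levels = alleles))
  df <- data.frame(allele_seq = alleles,
                   length = nchar(alleles),
                   n_forward = as.integer(fwd),
                   n_reverse = as.integer(rev),
                   stringsAsFactors = FALSE)
  df$n_total <- df$n_forward + df$n_reverse
  called <- df$n_total >= config$min_reads_per_allele
  if (config$both_strand_required) {
    called <- called & df$n_forward >= 1L & df$n_reverse >= 1L
  }
  df <- df[called, , drop = FALSE]
  df <- df[order(-df$n_total, -df$length, df$allele_seq), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Call zygosity, haplotype and minor alleles at one locus
#'
#' With depth below `min_locus_depth` the locus is left ungenotyped. The
#' most common called allele is the first haplotype allele; the second most
#' common joins the haplotype (heterozygous call) iff its support exceeds
#' `het_total_fraction` of the total reads supporting called alleles at the
#' locus, or `het_major_fraction` of the major allele's support. Every
#' other called allele -- including a second allele that fails the
#' heterozygote test -- is a minor allele. (The heterozygote-rule
#' denominator is the binned, allele-supporting read total rather than the
#' raw retained depth: reads whose repeat bases carry errors support no
#' called allele, and counting them would make the 25% rule drop true
#' second alleles as the error rate grows.)
#'
#' @param alleles Called alleles from [tally_alleles()] (support-sorted).
#' @param depth Locus depth: the number of retained observations.
#' @param config A [caller_config()].
#' @param locus_id Optional locus identifier carried into the result.
#' @return An object of class `smv_locus_call`: list with `locus_id`,
#'   `depth`, `zygosity` ("homozygous", "heterozygous" or "uncalled"),
#'   `haplotype` and `minor` allele data frames, `n_alleles_total`, and
#'   `reason` (NA, "low_depth" or "no_alleles").
#' @export
call_locus <- function(alleles, depth, config = caller_config(),
                       locus_id = NA_character_) {
  stopifnot(depth >= 0)
  none <- alleles[0L, , drop = FALSE]
  res <- list(locus_id = locus_id, depth = as.integer(depth),
              zygosity = "uncalled", haplotype = none, minor = none,
              n_alleles_total = 0L, reason = NA_character_)
  if (depth < config$min_locus_depth) {
    res$reason <- "low_depth"
    class(res) <- "smv_locus_call"
    return(res)
  }
  if (nrow(alleles) == 0L) {
    res$reason <- "no_alleles"
    class(res) <- "smv_locus_call"
    return(res)
  }
  het <- FALSE
  if (nrow(alleles) >= 2L) {
    n1 <- alleles$n_total[1L]
    n2 <- alleles$n_total[2L]
    called_total <- sum(alleles$n_total)
    het <- n2 > config$het_total_fraction * called_total ||
      n2 > config$het_major_fraction * n1
  }
  n_hap <- if (het) 2L else 1L
  res$zygosity <- if (het) "heterozygous" else "homozygous"
  res$haplotype <- alleles[seq_len(n_hap), , drop = FALSE]
  res$minor <- alleles[setdiff(seq_len(nrow(alleles)), seq_len(n_hap)), ,
                       drop = FALSE]
  res$n_alleles_total <- nrow(alleles)
  class(res) <- "smv_locus_call"
  res
}

#' @export
print.smv_locus_call <- function(x, ...) {
  cat(sprintf("Locus %s: %s (depth %d, %d called allele%s)\n",
              x$locus_id, x$zygosity, x$depth, x$n_alleles_total,
              if (x$n_alleles_total == 1L) "" else "s"))
  invisible(x)
}

#' Extract observations for every catalogue locus
#'
#' Bulk counterpart of [extract_observations()]: assigns reads to loci with
#' one interval-overlap pass, then applies the per-locus read filters.
#'
#' @param alignments Alignment data frame or SAM/BAM path.
#' @param catalogue Catalogue data frame (sorted by position).
#' @param reference Reference sequences.
#' @param config A [caller_config()].
#' @return List with `observations` (all retained observations) and `loci`
#'   (per attempted locus: `locus_id`, `n_spanning`, `depth`). Loci with no
#'   spanning reads are absent.
#' @export
extract_sample_observations <- function(alignments, catalogue, reference,
                                        config = caller_config()) {
  aln <- .prep_alignments(alignments)
  reference <- load_reference(reference)
  F <- config$flank_length
  win <- GenomicRanges::GRanges(catalogue$chrom,
                                IRanges::IRanges(catalogue$start - F + 1L,
                                                 catalogue$end + F))
  reads <- GenomicRanges::GRanges(aln$chrom,
                                  IRanges::IRanges(aln$pos, aln$ref_end))
  hits <- GenomicRanges::findOverlaps(win, reads, type = "within")
  by_locus <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  seqs <- aln$seq; quals <- aln$qual; strands <- aln$strand
  mapqs <- aln$mapq; qnames <- aln$qname; poses <- aln$pos
  obs_list <- vector("list", length(by_locus))
  loci_idx <- as.integer(names(by_locus))
  for (k in seq_along(by_locus)) {
    i <- loci_idx[k]
    ri <- by_locus[[k]]
    obs_list[[k]] <- .extract_locus_obs(
      seqs = seqs[ri], quals = quals[ri], strands = strands[ri],
      mapqs = mapqs[ri], qnames = qnames[ri], poss = poses[ri],
      locus = catalogue[i, , drop = FALSE],
      refseq = reference[[catalogue$chrom[i]]], config = config)
  }
  obs <- do.call(rbind, obs_list)
  if (is.null(obs)) {
    obs <- data.frame(locus_id = character(0), allele_seq = character(0),
                      strand = character(0), read_name = character(0),
                      stringsAsFactors = FALSE)
  }
  loci <- data.frame(locus_id = catalogue$locus_id[loci_idx],
                     n_spanning = lengths(by_locus),
                     depth = vapply(obs_list, nrow, integer(1L)),
                     stringsAsFactors = FALSE)
  list(observations = obs, loci = loci,
       n_malformed = attr(aln, "n_malformed"))
}

#' Call all loci from extracted observations
#'
#' @param extraction Result of [extract_sample_observations()].
#' @param catalogue Catalogue data frame (for locus coordinates in output).
#' @param config A [caller_config()].
#' @return An object of class `smv_calls`: list with `calls` (one row per
#'   attempted locus), `alleles` (one row per called allele, with `role`
#'   "haplotype1"/"haplotype2"/"minor" and support rank), and `log`.
#' @export
call_from_observations <- function(extraction, catalogue,
                                   config = caller_config()) {
  loci <- extraction$loci
  obs_by_locus <- split(extraction$observations,
                        extraction$observations$locus_id)
  n <- nrow(loci)
  zyg <- character(n); nall <- integer(n); nmin <- integer(n)
  reason <- rep(NA_character_, n)
  allele_rows <- vector("list", n)
  for (k in seq_len(n)) {
    lid <- loci$locus_id[k]
    ob <- obs_by_locus[[lid]]
    depth <- loci$depth[k]
    tal <- tally_alleles(ob, config)
    cl <- call_locus(tal, depth, config, locus_id = lid)
    zyg[k] <- cl$zygosity
    nall[k] <- cl$n_alleles_total
    nmin[k] <- nrow(cl$minor)
    reason[k] <- cl$reason
    if (cl$n_alleles_total > 0L) {
      af <- rbind(cl$haplotype, cl$minor)
      af$role <- c(paste0("haplotype", seq_len(nrow(cl$haplotype))),
                   rep("minor", nrow(cl$minor)))
      af$rank <- seq_len(nrow(af))
      af$locus_id <- lid
      allele_rows[[k]] <- af
    }
  }
  calls <- data.frame(locus_id = loci$locus_id,
                      depth = loci$depth,
                      zygosity = zyg,
                      n_alleles_total = nall,
                      n_minor = nmin,
                      reason = reason,
                      stringsAsFactors = FALSE)
  ci <- match(calls$locus_id, catalogue$locus_id)
  calls$chrom <- catalogue$chrom[ci]
  calls$start <- catalogue$start[ci]
  calls$end <- catalogue$end[ci]
  alleles <- do.call(rbind, allele_rows)
  if (is.null(alleles)) {
    alleles <- data.frame(allele_seq = character(0), length = integer(0),
                          n_forward = integer(0), n_reverse = integer(0),
                          n_total = integer(0), role = character(0),
                          rank = integer(0), locus_id = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(alleles) <- NULL
  lg <- list(n_attempted = n,
             n_genotyped = sum(zyg %in% c("homozygous", "heterozygous")),
             n_with_minor = sum(nmin > 0L),
             n_malformed_records = extraction$n_malformed)
  structure(list(calls = calls, alleles = alleles, log = lg),
            class = "smv_calls")
}

#' Call a whole sample
#'
#' One call per catalogue locus with at least one spanning read, in
#' catalogue order. The result is deterministic in its inputs.
#'
#' @inheritParams extract_sample_observations
#' @param verbose Emit a summary message (default FALSE).
#' @return An `smv_calls` object; see [call_from_observations()].
#' @export
call_sample <- function(alignments, catalogue, reference,
                        config = caller_config(), verbose = FALSE) {
  ex <- extract_sample_observations(alignments, catalogue, reference, config)
  res <- call_from_observations(ex, catalogue, config)
  if (verbose) {
    message(sprintf(
      "called %d/%d loci (genotyped %d, with minor alleles %d)",
      res$log$n_attempted, nrow(catalogue), res$log$n_genotyped,
      res$log$n_with_minor))
  }
  res
}

#' @export
print.smv_calls <- function(x, ...) {
  cat(sprintf("smv_calls: %d loci attempted, %d genotyped, %d with minor alleles\n",
              x$log$n_attempted, x$log$n_genotyped, x$log$n_with_minor))
  invisible(x)
}

#' Write per-locus calls to TSV
#'
#' One row per locus: coordinates, depth, zygosity, then per-allele columns
#' (`length:n_forward:n_reverse`, support-ordered, comma-separated).
#'
#' @param calls An `smv_calls` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  cl <- calls$calls
  al <- calls$alleles
  packed <- vapply(cl$locus_id, function(lid) {
    a <- al[al$locus_id == lid, , drop = FALSE]
    if (nrow(a) == 0L) return(".")
    paste(sprintf("%d:%d:%d", a$length, a$n_forward, a$n_reverse),
          collapse = ",")
  }, character(1L), USE.NAMES = FALSE)
  out <- data.frame(cl[c("chrom", "start", "end", "locus_id", "depth",
                         "zygosity", "n_alleles_total", "n_minor")],
                    alleles = packed, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
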