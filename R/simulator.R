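# Read simulator: synthetic references with planted microsatellites, diploid
# truth with subclonal minor alleles, error-bearing paired-end reads, and
# evaluation of caller output against truth.

#' Simulation configuration
#'
#' Study conditions for the error-characterization simulations. Defaults
#' emulate an exome-like run: 2x100 bp paired-end reads, mean spanning depth
#' 50 with gamma-overdispersed per-locus coverage, per-base error 1% split
#' 90:10 between substitutions and 1-nt indels, 5% heterozygous loci with
#' in-phase second alleles, and planted loci of motif length 1-6 and total
#' length 8-44 nt separated by non-repetitive flanks.
#'
#' @param n_loci Number of planted microsatellite loci.
#' @param motif_length_weights Sampling weights for motif lengths 1-6.
#' @param copies_range Integer pair bounding motif copy number.
#' @param max_locus_length Maximum planted locus length (nt).
#' @param flank_length_genomic Non-repetitive flank between loci (nt). Must
#'   be large enough that a mate pair never spans a neighbouring locus
#'   (default 400 with insert 300).
#' @param read_length Read length (default 100).
#' @param mean_depth Mean number of repeat-spanning reads per locus.
#' @param depth_dispersion Gamma shape of the per-locus depth mixing
#'   distribution in `"overdispersed"` mode; larger is closer to uniform.
#' @param coverage_mode `"overdispersed"` (gamma-Poisson, in-house-style) or
#'   `"uniform"` (Poisson, wgsim-style).
#' @param per_base_error Per-nucleotide error rate (the study sweeps
#'   0.005-0.05).
#' @param error_indel_fraction Fraction of errors that are 1-nt indels
#'   (default 0.1; the rest are substitutions).
#' @param het_fraction Fraction of loci planted heterozygous (default 0.05).
#' @param minor_planting_rate Fraction of loci given one subclonal minor
#'   allele (default 0; the error sweep uses error-only truth).
#' @param minor_read_fraction_range Range of planted minor-allele read
#'   fractions; the maximum must stay below the 0.25 heterozygote threshold.
#' @param insert_size Outer fragment size for mate placement (default 300).
#' @param base_quality Phred quality written for every base (default 35).
#' @param error_low_quality_prob Probability that a substitution-error base
#'   is written with `low_quality` instead (default 0, so quality filtering
#'   can be studied independently of the read-count threshold).
#' @param low_quality Phred quality used for flagged error bases.
#' @param mapq Mapping quality written for every alignment record.
#' @param seed Integer seed; all simulator stages derive from it.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_loci = 2000L,
                              motif_length_weights = c(0.40, 0.25, 0.15, 0.10, 0.06, 0.04),
                              copies_range = c(3L, 44L),
                              max_locus_length = 44L,
                              flank_length_genomic = 400L,
                              read_length = 100L,
                              mean_depth = 50,
                              depth_dispersion = 10,
                              coverage_mode = c("overdispersed", "uniform"),
                              per_base_error = 0.01,
                              error_indel_fraction = 0.1,
                              het_fraction = 0.05,
                              minor_planting_rate = 0,
                              minor_read_fraction_range = c(0.05, 0.15),
                              insert_size = 300L,
                              base_quality = 35L,
                              error_low_quality_prob = 0,
                              low_quality = 20L,
                              mapq = 60L,
                              seed = 1L) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(n_loci >= 1L, length(motif_length_weights) == 6L,
            all(motif_length_weights >= 0), sum(motif_length_weights) > 0,
            copies_range[1L] >= 1L, copies_range[2L] >= copies_range[1L],
            max_locus_length >= 8L, read_length >= 50L,
            mean_depth > 0, depth_dispersion > 0,
            per_base_error >= 0, per_base_error <= 0.25,
            error_indel_fraction >= 0, error_indel_fraction <= 1,
            het_fraction >= 0, het_fraction <= 1,
            minor_planting_rate >= 0, minor_planting_rate <= 1,
            minor_read_fraction_range[1L] > 0,
            minor_read_fraction_range[2L] >= minor_read_fraction_range[1L],
            minor_read_fraction_range[2L] < 0.25,
            flank_length_genomic >= insert_size + 2L * read_length - 100L,
            insert_size >= 2L * read_length,
            seed == as.integer(seed))
  if (per_base_error > 0.05) {
    warning("per_base_error above the characterized 0.5%-5% sweep range")
  }
  structure(list(n_loci = as.integer(n_loci),
                 motif_length_weights = motif_length_weights,
                 copies_range = as.integer(copies_range),
                 max_locus_length = as.integer(max_locus_length),
                 flank_length_genomic = as.integer(flank_length_genomic),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 coverage_mode = coverage_mode,
                 per_base_error = per_base_error,
                 error_indel_fraction = error_indel_fraction,
                 het_fraction = het_fraction,
                 minor_planting_rate = minor_planting_rate,
                 minor_read_fraction_range = minor_read_fraction_range,
                 insert_size = as.integer(insert_size),
                 base_quality = as.integer(base_quality),
                 error_low_quality_prob = error_low_quality_prob,
                 low_quality = as.integer(low_quality),
                 mapq = as.integer(mapq),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

.rand_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

.rand_primitive_motif <- function(m) {
  repeat {
    u <- .rand_dna(m)
    if (.is_primitive_motif(u)) return(u)
  }
}

# a base guaranteed to differ from `b`
.other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(.BASES, x), 1L), character(1L),
         USE.NAMES = FALSE)
}

#' Build a synthetic reference with planted microsatellites
#'
#' Plants `config$n_loci` perfect tandem repeats separated by random
#' non-repetitive flanks on a single synthetic chromosome. The three flank
#' bases adjacent to each locus are forced to mismatch the repeat's periodic
#' continuation so that the planted boundaries are exact, and the assembled
#' reference is re-scanned: any flank that by chance contains (or creates at
#' a junction) a catalogue-grade repeat is regenerated until the scanner
#' recovers exactly the planted catalogue.
#'
#' @param config A [simulation_config()].
#' @return List with `reference` (named character vector, one chromosome)
#'   and `catalogue` (planted loci; standard catalogue columns plus the
#'   planted phase `unit`).
#' @export
build_synthetic_reference <- function(config = simulation_config()) {
  set.seed(config$seed)
  n <- config$n_loci
  w <- config$motif_length_weights
  m <- sample(1:6, n, replace = TRUE, prob = w)
  unit <- vapply(m, .rand_primitive_motif, character(1L))
  lo <- pmax(config$copies_range[1L], ceiling(8L / m))
  hi <- pmax(lo, pmin(config$copies_range[2L], config$max_locus_length %/% m))
  # genomic MST length spectra decay sharply with length: truncated
  # geometric on copies above the minimum
  copies <- pmin(lo + stats::rgeom(n, prob = 0.25), hi)
  locus_seq <- strrep(unit, copies)
  len <- nchar(locus_seq)
  fl <- config$flank_length_genomic
  flanks <- vapply(rep(fl, n + 1L), .rand_dna, character(1L))
  flanks <- .fix_junctions(flanks, unit, len, m)
  chrom <- "sim_chr1"
  for (iter in 1:10) {
    parts <- character(2L * n + 1L)
    parts[seq(1L, 2L * n + 1L, by = 2L)] <- flanks
    parts[seq(2L, 2L * n, by = 2L)] <- locus_seq
    start0 <- cumsum(c(0L, nchar(parts)))[seq(2L, 2L * n, by = 2L)]
    end0 <- start0 + len
    refstr <- paste(parts, collapse = "")
    cand <- scan_tandem_repeats(stats::setNames(refstr, chrom))
    key <- paste(cand$start, cand$end)
    planted_key <- paste(start0, end0)
    # random flanks legitimately contain incidental short repeats (as real
    # genomes do); they are absent from the emitted catalogue and harmless
    # unless they encroach on a planted locus neighbourhood. Demand that
    # every planted interval is recovered exactly and that no other
    # candidate comes within `margin` nt of a planted boundary.
    margin <- 10L
    near <- rep(FALSE, nrow(cand))
    for (j in seq_len(nrow(cand))) {
      near[j] <- any(cand$start[j] < end0 + margin &
                       cand$end[j] > start0 - margin)
    }
    bad <- near & !(key %in% planted_key)
    if (!any(bad) && all(planted_key %in% key)) break
    # regenerate every flank intersecting an offending candidate
    fstart0 <- cumsum(c(0L, nchar(parts)))[seq(1L, 2L * n + 1L, by = 2L)]
    fend0 <- fstart0 + fl
    redo <- unique(unlist(lapply(which(bad), function(j) {
      which(fstart0 < cand$end[j] + margin & fend0 > cand$start[j] - margin)
    })))
    miss <- which(!(planted_key %in% key))
    redo <- unique(c(redo, miss, miss + 1L))
    for (fi in redo) flanks[fi] <- .rand_dna(fl)
    flanks <- .fix_junctions(flanks, unit, len, m)
    if (iter == 10L) stop("could not build a clean synthetic reference")
  }
  reference <- stats::setNames(refstr, chrom)
  catalogue <- data.frame(chrom = chrom, start = start0, end = end0,
                          motif = canonical_motif(unit),
                          copies = as.numeric(copies),
                          purity = 1,
                          ref_length = len,
                          locus_id = sprintf("%s_%d_%d", chrom, start0, end0),
                          unit = unit,
                          stringsAsFactors = FALSE)
  list(reference = reference, catalogue = catalogue)
}

# Constrain the flank bases adjacent to each locus: the 3 bases on each
# side must break the repeat's periodic continuation (so the planted
# boundary is exact), and the 7-nt anchor region next to the locus must not
# occur anywhere inside the periodic repeat (so flank anchors are
# unambiguous in reads). flanks[i] precedes locus i; flanks[i+1] follows it.
.fix_junctions <- function(flanks, unit, len, m) {
  n <- length(unit)
  fl <- nchar(flanks[1L])
  uch <- strsplit(unit, "", fixed = TRUE)
  aw <- 7L
  for (i in seq_len(n)) {
    u <- uch[[i]]
    mi <- m[i]
    # long enough to contain any in-repeat occurrence of a 7-mer at any phase
    rep_str <- strrep(unit[i], (len[i] + 2L * aw) %/% mi + 2L)
    lf <- flanks[i]
    repeat {
      for (j in 1:3) {
        expected <- u[((-j) %% mi) + 1L]
        p <- fl - j + 1L
        if (substr(lf, p, p) == expected) {
          substr(lf, p, p) <- .other_base(expected)
        }
      }
      anchor <- substr(lf, fl - aw + 1L, fl)
      if (!grepl(anchor, rep_str, fixed = TRUE)) break
      substr(lf, fl - aw + 1L, fl) <- .rand_dna(aw)
    }
    flanks[i] <- lf
    rf <- flanks[i + 1L]
    repeat {
      for (j in 1:3) {
        expected <- u[((len[i] + j - 1L) %% mi) + 1L]
        if (substr(rf, j, j) == expected) {
          substr(rf, j, j) <- .other_base(expected)
        }
      }
      anchor <- substr(rf, 1L, aw)
      if (!grepl(anchor, rep_str, fixed = TRUE)) break
      substr(rf, 1L, aw) <- .rand_dna(aw)
    }
    flanks[i + 1L] <- rf
  }
  flanks
}

#' Assign diploid truth and subclonal minor alleles to planted loci
#'
#' A `het_fraction` share of loci receives a second haplotype allele that
#' differs by an in-phase change of 1-2 motif units (so a dimer changes by
#' 2N nucleotides); a `minor_planting_rate` share receives one subclonal
#' in-phase allele at a read fraction drawn from
#' `minor_read_fraction_range`. Haplotype read fractions are 1.0
#' (homozygous) or 0.5/0.5 (heterozygous), scaled down by any planted minor
#' mass.
#'
#' @param catalogue Planted catalogue from [build_synthetic_reference()].
#' @param config A [simulation_config()].
#' @return Truth data frame: `locus_id`, `zygosity_truth`, `allele1`,
#'   `allele2`, `frac1`, `frac2`, `minor_allele`, `minor_frac`.
#' @export
assign_truth <- function(catalogue, config = simulation_config()) {
  set.seed(config$seed + 1L)
  n <- nrow(catalogue)
  unit <- catalogue$unit
  m <- nchar(unit)
  len <- catalogue$ref_length
  allele1 <- strrep(unit, len %/% m)
  is_het <- stats::runif(n) < config$het_fraction
  allele2 <- rep(NA_character_, n)
  for (i in which(is_het)) {
    k <- sample(c(1L, 2L), 1L, prob = c(0.8, 0.2))
    sgn <- sample(c(-1L, 1L), 1L)
    copies2 <- len[i] %/% m[i] + sgn * k
    if (copies2 < 1L) copies2 <- len[i] %/% m[i] + k
    allele2[i] <- strrep(unit[i], copies2)
  }
  planted <- stats::runif(n) < config$minor_planting_rate
  minor_allele <- rep(NA_character_, n)
  minor_frac <- rep(NA_real_, n)
  rng <- config$minor_read_fraction_range
  for (i in which(planted)) {
    existing <- c(nchar(allele1[i]), nchar(allele2[i]))
    for (k in sample(c(-1L, 1L, -2L, 2L))) {
      la <- len[i] + k * m[i]
      if (la >= m[i] && !(la %in% existing)) {
        minor_allele[i] <- strrep(unit[i], la %/% m[i])
        break
      }
    }
    minor_frac[i] <- stats::runif(1L, rng[1L], rng[2L])
  }
  mf <- ifelse(is.na(minor_frac), 0, minor_frac)
  frac1 <- ifelse(is_het, (1 - mf) / 2, 1 - mf)
  frac2 <- ifelse(is_het, (1 - mf) / 2, 0)
  data.frame(locus_id = catalogue$locus_id,
             zygosity_truth = ifelse(is_het, "heterozygous", "homozygous"),
             allele1 = allele1, allele2 = allele2,
             frac1 = frac1, frac2 = frac2,
             minor_allele = minor_allele, minor_frac = minor_frac,
             stringsAsFactors = FALSE)
}

#' Generate error-bearing paired-end reads over planted loci
#'
#' Every locus receives a number of repeat-spanning reads drawn from the
#' configured coverage model; each spanning read's allele is sampled from
#' the truth fractions, and its mate is placed in the neighbouring flank
#' (mates never span a repeat, so spanning depth equals the coverage draw).
#' Substitution errors occur at rate
#' `per_base_error * (1 - error_indel_fraction)` per base and 1-nt indels at
#' `per_base_error * error_indel_fraction`. Alignment positions, CIGAR,
#' flags and mapping quality are emitted directly (alignment is bypassed by
#' construction).
#'
#' @param reference Named character vector from [build_synthetic_reference()].
#' @param catalogue Planted catalogue.
#' @param truth Truth table from [assign_truth()].
#' @param config A [simulation_config()].
#' @return List with `alignments` (data frame of SAM-like records) and
#'   `spanning` (per-read bookkeeping: locus index and sampled allele).
#' @export
generate_reads <- function(reference, catalogue, truth,
                           config = simulation_config()) {
  set.seed(config$seed + 2L)
  refstr <- reference[[catalogue$chrom[1L]]]
  n <- nrow(catalogue)
  rl <- config$read_length
  buf <- 10L
  # per-locus spanning depth
  depth <- switch(config$coverage_mode,
    uniform = stats::rpois(n, config$mean_depth),
    overdispersed = stats::rpois(n, stats::rgamma(
      n, shape = config$depth_dispersion,
      rate = config$depth_dispersion / config$mean_depth)))
  li <- rep.int(seq_len(n), depth)
  N <- length(li)
  if (N == 0L) stop("no reads generated; increase mean_depth")
  # allele choice per read: 1 = allele1, 2 = allele2, 3 = planted minor
  mf <- ifelse(is.na(truth$minor_frac), 0, truth$minor_frac)
  u <- stats::runif(N)
  p1 <- truth$frac1[li]
  p2 <- truth$frac2[li]
  which_allele <- 1L + (u >= p1) + (u >= p1 + p2)
  allele <- truth$allele1[li]
  allele[which_allele == 2L] <- truth$allele2[li][which_allele == 2L]
  allele[which_allele == 3L] <- truth$minor_allele[li][which_allele == 3L]
  la <- nchar(allele)
  lr <- catalogue$ref_length[li]
  start0 <- catalogue$start[li]
  end0 <- catalogue$end[li]
  # local template: 200 nt of reference flank, the allele, 200 nt flank
  left <- substring(refstr, start0 - 200L + 1L, start0)
  right <- substring(refstr, end0 + 1L, end0 + 200L)
  tpl <- paste0(left, allele, right)
  # read start within template: spans allele plus a 7-nt anchor margin
  rs_lo <- (200L + la + 7L) - rl + 1L
  rs_hi <- rep.int(194L, N)   # left anchor ends 7 nt before the repeat
  rs <- rs_lo + floor(stats::runif(N) * (rs_hi - rs_lo + 1L))
  raw_span <- substring(tpl, rs, rs + rl + buf - 1L)
  pos <- (start0 - 200L) + rs            # 1-based SAM position
  nL <- 201L - rs
  d <- la - lr
  cig <- character(N)
  cig[d == 0L] <- paste0(rl, "M")
  ip <- d > 0L
  cig[ip] <- paste0(nL[ip] + lr[ip], "M", d[ip], "I",
                    rl - nL[ip] - la[ip], "M")
  im <- d < 0L
  cig[im] <- paste0(nL[im] + la[im], "M", -d[im], "D",
                    rl - nL[im] - la[im], "M")
  fwd <- stats::runif(N) < 0.5
  gap <- config$insert_size - rl
  mpos <- ifelse(fwd, pos + gap, pos - gap)
  raw_mate <- substring(refstr, mpos, mpos + rl + buf - 1L)
  # sequencing errors on both mates
  raw <- .apply_read_errors(c(raw_span, raw_mate), config)
  qual <- raw$qual
  seqs <- raw$seq
  seq_span <- seqs[seq_len(N)]
  seq_mate <- seqs[N + seq_len(N)]
  qual_span <- qual[seq_len(N)]
  qual_mate <- qual[N + seq_len(N)]
  chrom <- catalogue$chrom[1L]
  qname <- sprintf("simr%07d", seq_len(N))
  tlen <- ifelse(fwd, config$insert_size, -config$insert_size)
  alignments <- data.frame(
    qname = c(qname, qname),
    flag = c(ifelse(fwd, 99L, 83L), ifelse(fwd, 147L, 163L)),
    chrom = chrom,
    pos = c(pos, mpos),
    mapq = config$mapq,
    cigar = c(cig, rep.int(paste0(rl, "M"), N)),
    rnext = "=",
    pnext = c(mpos, pos),
    tlen = c(tlen, -tlen),
    seq = c(seq_span, seq_mate),
    qual = c(qual_span, qual_mate),
    stringsAsFactors = FALSE)
  spanning <- data.frame(qname = qname, locus_id = catalogue$locus_id[li],
                         allele = allele, forward = fwd,
                         stringsAsFactors = FALSE)
  list(alignments = alignments, spanning = spanning)
}

# Apply substitution and 1-nt indel errors to raw (read_length + buffer)
# strings, then cut to read_length. Returns seq and qual character vectors.
.apply_read_errors <- function(x, config) {
  rl <- config$read_length
  nx <- length(x)
  Lr <- nchar(x[1L])
  qhi <- rawToChar(as.raw(33L + config$base_quality))
  qlo <- rawToChar(as.raw(33L + config$low_quality))
  qual <- rep.int(strrep(qhi, rl), nx)
  p_sub <- config$per_base_error * (1 - config$error_indel_fraction)
  p_ind <- config$per_base_error * config$error_indel_fraction
  low_rp <- integer(0)
  low_oo <- integer(0)
  if (p_sub > 0) {
    k <- stats::rbinom(1L, nx * Lr, p_sub)
    if (k > 0L) {
      loc <- sample.int(nx * Lr, k)
      r <- (loc - 1L) %/% Lr + 1L
      o <- (loc - 1L) %% Lr + 1L
      shift <- sample.int(3L, k, replace = TRUE)
      if (config$error_low_quality_prob > 0) {
        mark <- stats::runif(k) < config$error_low_quality_prob & o <= rl
        low_rp <- r[mark]
        low_oo <- o[mark]
      }
      while (length(r)) {
        first <- !duplicated(r)
        rr <- r[first]; oo <- o[first]; ss <- shift[first]
        cur <- substr(x[rr], oo, oo)
        idx <- match(cur, .BASES)
        nb <- .BASES[((idx - 1L + ss) %% 4L) + 1L]
        tmp <- x[rr]
        substr(tmp, oo, oo) <- nb
        x[rr] <- tmp
        r <- r[!first]; o <- o[!first]; shift <- shift[!first]
      }
    }
  }
  if (p_ind > 0) {
    k <- stats::rbinom(1L, nx * Lr, p_ind)
    if (k > 0L) {
      loc <- sample.int(nx * Lr, k)
      r <- (loc - 1L) %/% Lr + 1L
      o <- (loc - 1L) %% Lr + 1L
      ins <- stats::runif(k) < 0.5
      base <- sample(.BASES, k, replace = TRUE)
      for (g in split(seq_len(k), r)) {
        ri <- r[g[1L]]
        s <- x[ri]
        ord <- g[order(o[g], decreasing = TRUE)]
        for (j in ord) {
          if (ins[j]) {
            s <- paste0(substr(s, 1L, o[j] - 1L), base[j],
                        substr(s, o[j], nchar(s)))
          } else {
            s <- paste0(substr(s, 1L, o[j] - 1L),
                        substr(s, o[j] + 1L, nchar(s)))
          }
        }
        x[ri] <- s
      }
    }
  }
  out <- substr(x, 1L, rl)
  short <- nchar(out) < rl
  if (any(short)) {
    out[short] <- paste0(out[short],
                         strrep("N", rl - nchar(out[short])))
  }
  if (length(low_rp)) {
    for (i in seq_along(low_rp)) {
      q <- qual[low_rp[i]]
      substr(q, low_oo[i], low_oo[i]) <- qlo
      qual[low_rp[i]] <- q
    }
  }
  list(seq = out, qual = qual)
}

#' Run the full simulator
#'
#' Builds the reference, assigns truth, generates reads, and (optionally)
#' writes reference FASTA, catalogue TSV, truth TSV, a coordinate-sorted SAM
#' and paired FASTQ files to `dir`.
#'
#' @param config A [simulation_config()].
#' @param dir Optional output directory; created if missing.
#' @return List with `reference`, `catalogue`, `truth`, `alignments`,
#'   `spanning`, and (when `dir` is given) `files`.
#' @export
simulate_sample <- function(config = simulation_config(), dir = NULL) {
  ref <- build_synthetic_reference(config)
  truth <- assign_truth(ref$catalogue, config)
  reads <- generate_reads(ref$reference, ref$catalogue, truth, config)
  out <- list(reference = ref$reference, catalogue = ref$catalogue,
              truth = truth, alignments = reads$alignments,
              spanning = reads$spanning)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      reference = file.path(dir, "reference.fa"),
      catalogue = file.path(dir, "catalogue.tsv"),
      truth = file.path(dir, "truth.tsv"),
      sam = file.path(dir, "reads.sam"),
      fastq1 = file.path(dir, "reads_1.fastq"),
      fastq2 = file.path(dir, "reads_2.fastq"))
    write_reference_fasta(ref$reference, files$reference)
    write_catalogue(ref$catalogue, files$catalogue)
    write_truth(truth, files$truth)
    write_sam(reads$alignments, nchar(ref$reference), files$sam)
    write_paired_fastq(reads$alignments, files$fastq1, files$fastq2)
    out$files <- files
  }
  out
}

#' Write a truth table to TSV
#' @param truth Truth data frame from [assign_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = ".")
  invisible(path)
}

#' Read a truth table TSV
#' @param path Path written by [write_truth()].
#' @return Truth data frame.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          na.strings = ".")
  df
}

#' Evaluate caller output against simulator truth
#'
#' Reports (a) zygosity accuracy over genotyped loci, (b) the fraction of
#' genotyped loci at which every called allele is a truth allele (with
#' error-only truth this is the fraction of loci without false minor
#' alleles), (c) sensitivity of planted-minor recovery, and (d) the mean
#' depth per observed allele count.
#'
#' @param calls Result of [call_sample()] / [call_from_observations()].
#' @param truth Truth data frame.
#' @return An object of class `smv_evaluation` (a list).
#' @export
evaluate_against_truth <- function(calls, truth) {
  cl <- calls$calls
  al <- calls$alleles
  unmatched <- sum(!(cl$locus_id %in% truth$locus_id))
  if (unmatched > 0L) {
    warning(sprintf("%d called loci have no truth record; excluded", unmatched))
    cl <- cl[cl$locus_id %in% truth$locus_id, , drop = FALSE]
  }
  ti <- match(cl$locus_id, truth$locus_id)
  genotyped <- cl$zygosity %in% c("homozygous", "heterozygous")
  gcl <- cl[genotyped, , drop = FALSE]
  gti <- ti[genotyped]
  zyg_acc <- if (nrow(gcl)) mean(gcl$zygosity == truth$zygosity_truth[gti]) else NA_real_
  # false alleles: any called allele sequence absent from the truth set
  al <- al[al$locus_id %in% gcl$locus_id, , drop = FALSE]
  ati <- match(al$locus_id, truth$locus_id)
  is_true <- al$allele_seq == truth$allele1[ati] |
    (!is.na(truth$allele2[ati]) & al$allele_seq == truth$allele2[ati]) |
    (!is.na(truth$minor_allele[ati]) & al$allele_seq == truth$minor_allele[ati])
  n_false_by_locus <- tapply(!is_true, al$locus_id, sum)
  clean <- rep(TRUE, nrow(gcl))
  names(clean) <- gcl$locus_id
  hit <- intersect(names(n_false_by_locus), names(clean))
  clean[hit] <- n_false_by_locus[hit] == 0L
  false_free <- if (nrow(gcl)) mean(clean) else NA_real_
  # planted-minor sensitivity
  planted <- !is.na(truth$minor_allele[gti])
  sens <- NA_real_
  if (any(planted)) {
    pl <- gcl$locus_id[planted]
    want <- truth$minor_allele[gti][planted]
    got <- vapply(seq_along(pl), function(i) {
      any(al$allele_seq[al$locus_id == pl[i]] == want[i])
    }, logical(1L))
    sens <- mean(got)
  }
  structure(list(n_loci_called = nrow(cl),
                 n_genotyped = nrow(gcl),
                 n_truth_unmatched = unmatched,
                 zygosity_accuracy = zyg_acc,
                 false_allele_free_fraction = false_free,
                 planted_minor_sensitivity = sens,
                 depth_by_allele_count = depth_by_allele_count(cl)),
            class = "smv_evaluation")
}

#' @export
print.smv_evaluation <- function(x, ...) {
  cat("Simulation evaluation\n")
  cat(sprintf("  loci called:          %d (genotyped %d)\n",
              x$n_loci_called, x$n_genotyped))
  cat(sprintf("  zygosity accuracy:    %.4f%%\n", 100 * x$zygosity_accuracy))
  cat(sprintf("  false-allele-free:    %.2f%% of genotyped loci\n",
              100 * x$false_allele_free_fraction))
  if (!is.na(x$planted_minor_sensitivity)) {
    cat(sprintf("  planted-minor recall: %.2f%%\n",
                100 * x$planted_minor_sensitivity))
  }
  invisible(x)
}
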