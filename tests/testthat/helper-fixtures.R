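# Hand-built fixtures: a tiny reference with one dinucleotide repeat and a
# constructor for alignment records with controllable qualities.

# reference: 30 nt left flank, (AC)x6 repeat, 30 nt right flank
fixture_reference <- function() {
  left <- "TTGACGTAGGCTATTCGGAACTGGATCGTG"
  right <- "CATGGATCCGTTAACGGTCAGTCCTAGGTA"
  ref <- paste0(left, strrep("AC", 6L), right)
  list(reference = c(chrT = ref),
       locus = data.frame(chrom = "chrT", start = 30L, end = 42L,
                          motif = "AC", copies = 6, purity = 1,
                          ref_length = 12L, locus_id = "chrT_30_42",
                          stringsAsFactors = FALSE))
}

# one alignment record fully spanning the fixture repeat; the read copies
# the reference from `pos1` (1-based), with optional allele substitution
fixture_read <- function(ref, pos1 = 11L, len = 70L, allele = NULL,
                         strand = "+", mapq = 60L, qual_phred = 35L,
                         qname = "r1", low_qual_at = integer(0),
                         low_qual_phred = 20L) {
  refstr <- ref$reference[[1L]]
  loc <- ref$locus
  if (is.null(allele)) {
    seq <- substr(refstr, pos1, pos1 + len - 1L)
  } else {
    leftpart <- substr(refstr, pos1, loc$start)
    rightpart <- substr(refstr, loc$end + 1L, pos1 + len - 1L +
                          (loc$ref_length - nchar(allele)))
    seq <- paste0(leftpart, allele, rightpart)
    seq <- substr(seq, 1L, len)
  }
  q <- strrep(rawToChar(as.raw(33L + qual_phred)), nchar(seq))
  for (p in low_qual_at) {
    substr(q, p, p) <- rawToChar(as.raw(33L + low_qual_phred))
  }
  data.frame(qname = qname,
             flag = if (strand == "+") 0L else 16L,
             chrom = loc$chrom, pos = pos1, mapq = mapq,
             cigar = paste0(nchar(seq), "M"),
             seq = seq, qual = q, strand = strand,
             stringsAsFactors = FALSE)
}

# n reads alternating strand, all clean and spanning
fixture_pileup <- function(ref, n, allele = NULL, qname_prefix = "p") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    fixture_read(ref, allele = allele,
                 strand = if (i %% 2L == 0L) "-" else "+",
                 qname = paste0(qname_prefix, i))
  }))
}

# minimal smv_calls-like object for profile-level tests
fixture_calls <- function(locus_ids, zygosity, n_minor,
                          depth = 50L,
                          n_alleles_total = NULL) {
  n <- length(locus_ids)
  if (is.null(n_alleles_total)) {
    n_alleles_total <- ifelse(zygosity == "heterozygous", 2L, 1L) + n_minor
  }
  calls <- data.frame(locus_id = locus_ids,
                      depth = rep_len(depth, n),
                      zygosity = zygosity,
                      n_alleles_total = n_alleles_total,
                      n_minor = n_minor,
                      reason = NA_character_,
                      stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 alleles = data.frame(allele_seq = character(0),
                                      length = integer(0),
                                      n_forward = integer(0),
                                      n_reverse = integer(0),
                                      n_total = integer(0),
                                      role = character(0), rank = integer(0),
                                      locus_id = character(0),
                                      stringsAsFactors = FALSE),
                 log = list()),
            class = "smv_calls")
}

# build a pair of smv_calls with controllable haplotypes and minors
fixture_pair_calls <- function(hap_a, hap_b, minors_a, minors_b) {
  n <- length(hap_a)
  ids <- sprintf("S%d", seq_len(n))
  mk <- function(hap, minors) {
    calls <- fixture_calls(ids,
                           ifelse(lengths(hap) == 2L, "heterozygous",
                                  "homozygous"),
                           n_minor = ifelse(minors, 1L, 0L))
    al <- do.call(rbind, lapply(seq_len(n), function(i) {
      seqs <- c(hap[[i]], if (minors[i]) "GGGGG")
      roles <- c(paste0("haplotype", seq_along(hap[[i]])),
                 if (minors[i]) "minor")
      data.frame(allele_seq = seqs, length = nchar(seqs),
                 n_forward = 5L, n_reverse = 5L, n_total = 10L,
                 role = roles, rank = seq_along(seqs), locus_id = ids[i],
                 stringsAsFactors = FALSE)
    }))
    calls$alleles <- al
    calls
  }
  list(a = mk(hap_a, minors_a), b = mk(hap_b, minors_b))
}
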