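# Alignment IO. Reading goes through Rsamtools (SAM files are converted to
# BAM with asBam, then scanned); SAM/FASTQ writing formats the records
# directly since the records originate in-memory.

#' Read alignments from SAM or BAM
#'
#' @param path Path to a `.sam` or `.bam` file. SAM files must carry `@SQ`
#'   header lines (files written by [write_sam()] do).
#' @return Data frame with columns `qname`, `flag`, `chrom`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `strand`.
#' @export
read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(path, param = param)[[1L]]
  df <- data.frame(qname = b$qname,
                   flag = b$flag,
                   chrom = as.character(b$rname),
                   pos = b$pos,
                   mapq = b$mapq,
                   cigar = b$cigar,
                   seq = as.character(b$seq),
                   qual = as.character(b$qual),
                   stringsAsFactors = FALSE)
  df$strand <- ifelse(bitwAnd(df$flag, 16L) > 0L, "-", "+")
  df
}

#' Write alignment records to a coordinate-sorted SAM file
#'
#' @param alignments Data frame with columns `qname`, `flag`, `chrom`,
#'   `pos`, `mapq`, `cigar`, `seq`, `qual` and optionally `rnext`, `pnext`,
#'   `tlen`.
#' @param seqlengths Named integer vector of reference sequence lengths
#'   (names are chromosome names) for the `@SQ` header.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, seqlengths, path) {
  a <- alignments
  if (is.null(a$rnext)) a$rnext <- "*"
  if (is.null(a$pnext)) a$pnext <- 0L
  if (is.null(a$tlen)) a$tlen <- 0L
  a <- a[order(a$chrom, a$pos), , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  a$qname, a$flag, a$chrom, a$pos, a$mapq, a$cigar,
                  a$rnext, a$pnext, a$tlen, a$seq, a$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write paired FASTQ files from alignment records
#'
#' First-of-pair reads (flag bit 0x40) go to `path1`, second-of-pair to
#' `path2`; reverse-strand records are reverse-complemented back to
#' sequencing orientation.
#'
#' @param alignments Alignment data frame (as produced by
#'   [generate_reads()]).
#' @param path1,path2 Output FASTQ paths for mate 1 and mate 2.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_paired_fastq <- function(alignments, path1, path2) {
  a <- alignments
  rev <- bitwAnd(a$flag, 16L) > 0L
  seqs <- a$seq
  quals <- a$qual
  if (any(rev)) {
    seqs[rev] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
    quals[rev] <- vapply(quals[rev], function(q) {
      paste(rev(strsplit(q, "", fixed = TRUE)[[1L]]), collapse = "")
    }, character(1L), USE.NAMES = FALSE)
  }
  first <- bitwAnd(a$flag, 64L) > 0L
  ord1 <- which(first)[order(a$qname[first])]
  ord2 <- which(!first)[order(a$qname[!first])]
  fq <- function(i, mate) {
    as.vector(rbind(sprintf("@%s/%d", a$qname[i], mate),
                    seqs[i], "+", quals[i]))
  }
  writeLines(fq(ord1, 1L), path1)
  writeLines(fq(ord2, 2L), path2)
  invisible(c(path1, path2))
}
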