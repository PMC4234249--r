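# Classification of non-major alleles relative to the locus's most common
# allele: SNP (same length, different sequence), expansion (longer) or
# contraction (shorter); length changes that are whole motif-unit multiples
# are flagged in-phase (the polymerase-slippage signature).

#' Classify one allele against the major allele
#'
#' @param major Major (most common) allele sequence, or an allele row with
#'   an `allele_seq` column.
#' @param other The allele to classify (must differ from `major`).
#' @param motif Locus motif (any rotation).
#' @return List with `kind` ("SNP", "expansion" or "contraction"),
#'   `length_delta` (nt, other minus major) and `in_phase` (TRUE when the
#'   length change is a nonzero whole multiple of the motif length).
#' @examples
#' classify_minor_allele("ACACACACAC", "ACACACACACAC", "AC")
#' @export
classify_minor_allele <- function(major, other, motif) {
  if (is.data.frame(major)) major <- major$allele_seq[1L]
  if (is.data.frame(other)) other <- other$allele_seq[1L]
  if (identical(major, other)) {
    stop("allele is identical to the major allele; nothing to classify",
         call. = FALSE)
  }
  delta <- nchar(other) - nchar(major)
  kind <- if (delta > 0L) "expansion" else if (delta < 0L) "contraction" else "SNP"
  list(kind = kind,
       length_delta = as.integer(delta),
       in_phase = delta != 0L && delta %% nchar(motif) == 0L)
}

# Vectorized classification of every non-major called allele.
# Returns one row per classified allele.
.classify_calls <- function(calls, catalogue, scope = c("minor_only",
                                                        "all_non_major")) {
  scope <- match.arg(scope)
  al <- calls$alleles
  if (nrow(al) == 0L) return(al[0L, , drop = FALSE])
  major <- al[al$role == "haplotype1", c("locus_id", "allele_seq")]
  names(major)[2L] <- "major_seq"
  roles <- if (scope == "minor_only") "minor" else c("haplotype2", "minor")
  sel <- al[al$role %in% roles, , drop = FALSE]
  if (nrow(sel) == 0L) return(sel)
  mi <- match(sel$locus_id, major$locus_id)
  sel$major_seq <- major$major_seq[mi]
  ci <- match(sel$locus_id, catalogue$locus_id)
  sel$motif_length <- nchar(catalogue$motif[ci])
  sel$length_delta <- sel$length - nchar(sel$major_seq)
  sel$kind <- ifelse(sel$length_delta > 0L, "expansion",
                     ifelse(sel$length_delta < 0L, "contraction", "SNP"))
  sel$in_phase <- sel$length_delta != 0L &
    sel$length_delta %% sel$motif_length == 0L
  sel
}

#' Variant spectrum of classified alleles
#'
#' Percentages of SNP, expansion and contraction alleles over all classified
#' alleles in scope, plus the percent of INDEL alleles whose length change
#' is in phase with the motif. `scope = "minor_only"` classifies only minor
#' alleles (the usual somatic-variation summary); `"all_non_major"` also
#' classifies second haplotype alleles.
#'
#' @param calls An `smv_calls` object.
#' @param catalogue Catalogue data frame.
#' @param scope `"minor_only"` (default) or `"all_non_major"`.
#' @return List with `n_alleles`, `pct_snp`, `pct_expansion`,
#'   `pct_contraction`, `pct_in_phase` (of INDEL alleles; NA when there are
#'   none), and the per-allele `table`. With zero classifiable alleles all
#'   percentages are NA and `empty` is TRUE.
#' @export
variant_spectrum <- function(calls, catalogue,
                             scope = c("minor_only", "all_non_major")) {
  cls <- .classify_calls(calls, catalogue, scope)
  if (nrow(cls) == 0L) {
    return(list(n_alleles = 0L, pct_snp = NA_real_, pct_expansion = NA_real_,
                pct_contraction = NA_real_, pct_in_phase = NA_real_,
                table = cls, empty = TRUE))
  }
  n <- nrow(cls)
  indel <- cls$kind != "SNP"
  list(n_alleles = n,
       pct_snp = 100 * mean(cls$kind == "SNP"),
       pct_expansion = 100 * mean(cls$kind == "expansion"),
       pct_contraction = 100 * mean(cls$kind == "contraction"),
       pct_in_phase = if (any(indel)) 100 * mean(cls$in_phase[indel]) else NA_real_,
       table = cls, empty = FALSE)
}

#' Motif-length spectrum of minor-allele loci
#'
#' Distribution of motif lengths (1-6) across loci carrying at least one
#' minor allele.
#'
#' @param calls An `smv_calls` object.
#' @param catalogue Catalogue data frame.
#' @return Data frame `motif_length`, `n_loci`, `pct` (percentages sum to
#'   100 over loci with minor alleles).
#' @export
motif_length_spectrum <- function(calls, catalogue) {
  cl <- calls$calls
  sel <- cl[cl$n_minor >= 1L, , drop = FALSE]
  ml <- nchar(catalogue$motif[match(sel$locus_id, catalogue$locus_id)])
  counts <- table(factor(ml, levels = 1:6))
  data.frame(motif_length = 1:6,
             n_loci = as.integer(counts),
             pct = if (nrow(sel)) 100 * as.integer(counts) / nrow(sel) else
               rep(NA_real_, 6L))
}
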