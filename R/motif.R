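#' Canonical form of a microsatellite motif
#'
#' Every rotation of a repeat unit describes the same tandem repeat
#' (e.g. "CA", "AC" both describe a CA-dinucleotide run), so motifs are
#' reported in a canonical form: the lexicographically minimal rotation.
#'
#' @param motif Character vector of DNA motifs (A/C/G/T, length 1 or more).
#' @return Character vector of canonical motifs, same length as `motif`.
#' @examples
#' canonical_motif("CA")            # "AC"
#' canonical_motif(c("AAC", "ACA", "CAA"))  # all "AAC"
#' @export
canonical_motif <- function(motif) {
  stopifnot(is.character(motif), length(motif) >= 1L)
  .check_dna(motif)
  vapply(motif, function(m) min(.rotations(m)), character(1L), USE.NAMES = FALSE)
}

.rotations <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(m)
  vapply(seq_len(n) - 1L, function(k) {
    paste0(substr(m, k + 1L, n), substr(m, 1L, k))
  }, character(1L))
}

.check_dna <- function(x, what = "motif") {
  bad <- !grepl("^[ACGT]+$", x)
  if (any(bad)) {
    stop(sprintf("%s must be a non-empty string over {A,C,G,T}; got %s",
                 what, deparse(x[bad][1L])), call. = FALSE)
  }
  invisible(x)
}

# TRUE when the motif is not itself a tandem repetition of a shorter unit
# ("ATAT" is period-2, not a primitive 4-mer).
.is_primitive_motif <- function(m) {
  n <- nchar(m)
  if (n == 1L) return(TRUE)
  divs <- seq_len(n - 1L)
  divs <- divs[n %% divs == 0L]
  for (d in divs) {
    if (strrep(substr(m, 1L, d), n %/% d) == m) return(FALSE)
  }
  TRUE
}

#' Sequence purity of a locus against a motif
#'
#' Purity is the fraction of positions in `locus_sequence` that match a
#' perfect, ungapped tandem repetition of `motif`, maximized over the
#' motif's rotations (equivalently, over all start phases of the periodic
#' pattern).
#'
#' @param locus_sequence DNA string (single locus sequence).
#' @param motif DNA motif string, no longer than the locus.
#' @return A number in \[0, 1\]; 1 iff the sequence is an exact tandem
#'   repetition of some rotation of the motif.
#' @examples
#' compute_purity("ACACACAC", "AC")  # 1
#' compute_purity("ACACATAC", "AC")  # 7/8
#' @export
compute_purity <- function(locus_sequence, motif) {
  stopifnot(length(locus_sequence) == 1L, length(motif) == 1L)
  .check_dna(locus_sequence, "locus_sequence")
  .check_dna(motif)
  L <- nchar(locus_sequence)
  m <- nchar(motif)
  if (m > L) stop("motif is longer than the locus sequence", call. = FALSE)
  s <- strsplit(locus_sequence, "", fixed = TRUE)[[1L]]
  best <- 0
  for (rot in .rotations(motif)) {
    tmpl <- rep_len(strsplit(rot, "", fixed = TRUE)[[1L]], L)
    best <- max(best, mean(s == tmpl))
  }
  best
}
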