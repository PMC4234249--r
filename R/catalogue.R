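# Microsatellite locus catalogue: detection, filtering, IO, and matched
# non-repeat control loci.

#' Catalogue configuration
#'
#' Thresholds used to build and filter the microsatellite (MST) catalogue.
#' A locus survives filtering when its length is at least `min_locus_length`
#' nucleotides, it holds at least `min_motif_copies` copies of its motif, and
#' its sequence purity is at least `min_purity`.
#'
#' @param min_locus_length Minimum locus length in nucleotides (default 8).
#' @param min_motif_copies Minimum motif copy number (default 3).
#' @param min_purity Minimum sequence purity in \[0, 1\] (default 0.85).
#' @param motif_length_range Integer pair, motif lengths considered
#'   (default 1-6).
#' @param non_mst_segment_length Length of non-MST control segments
#'   (default 15 nt).
#' @return An object of class `catalogue_config`.
#' @export
catalogue_config <- function(min_locus_length = 8L,
                             min_motif_copies = 3,
                             min_purity = 0.85,
                             motif_length_range = c(1L, 6L),
                             non_mst_segment_length = 15L) {
  stopifnot(min_locus_length > 0, min_motif_copies > 0,
            min_purity > 0, min_purity <= 1,
            length(motif_length_range) == 2L,
            motif_length_range[1L] >= 1L,
            motif_length_range[2L] >= motif_length_range[1L],
            non_mst_segment_length > 0)
  structure(list(min_locus_length = as.integer(min_locus_length),
                 min_motif_copies = as.numeric(min_motif_copies),
                 min_purity = as.numeric(min_purity),
                 motif_length_range = as.integer(motif_length_range),
                 non_mst_segment_length = as.integer(non_mst_segment_length)),
            class = "catalogue_config")
}

.empty_catalogue <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             motif = character(0), copies = numeric(0), purity = numeric(0),
             ref_length = integer(0), stringsAsFactors = FALSE)
}

#' Scan a reference for tandem-repeat candidate loci
#'
#' Built-in seed-and-extend detector. Seeds are maximal exact tandem runs of
#' a primitive 1-6 nt unit with an exact core of at least two copies (and at
#' least 4 nt). Each seed is extended one base at a time under the seed's
#' periodic template while the template-match fraction stays at or above
#' `config$min_purity`, stopping once two consecutive mismatches accumulate
#' at the growing end; terminal mismatches are then trimmed. Candidates shorter than
#' `config$min_locus_length` are dropped. Candidate intervals may overlap;
#' use [filter_and_dedupe()] to resolve them. Ambiguity codes (N) terminate
#' runs and never appear inside candidates.
#'
#' @param reference Reference sequences (FASTA path, `DNAStringSet`, or
#'   named character vector).
#' @param config A [catalogue_config()].
#' @return Data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `motif` (canonical), `copies`, `purity`, `ref_length`.
#' @export
scan_tandem_repeats <- function(reference, config = catalogue_config()) {
  reference <- load_reference(reference)
  out <- lapply(names(reference), function(chrom) {
    .scan_sequence(reference[[chrom]], chrom, config)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(.empty_catalogue())
  rownames(out) <- NULL
  out
}

.scan_sequence <- function(seqstr, chrom, config) {
  L <- nchar(seqstr)
  if (L == 0L) return(NULL)
  chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
  valid <- chars == "A" | chars == "C" | chars == "G" | chars == "T"
  mrange <- seq.int(config$motif_length_range[1L], config$motif_length_range[2L])
  minp <- config$min_purity
  rows <- list()
  nr <- 0L
  for (m in mrange) {
    if (L < 2L * m) next
    i <- seq_len(L - m)
    eq <- chars[i] == chars[i + m] & valid[i] & valid[i + m]
    r <- rle(eq)
    rends <- cumsum(r$lengths)
    rstarts <- rends - r$lengths + 1L
    need_run <- max(m, 4L - m)
    sel <- which(r$values & r$lengths >= need_run)
    for (k in sel) {
      i0 <- rstarts[k]
      unit <- substr(seqstr, i0, i0 + m - 1L)
      if (!.is_primitive_motif(unit)) next
      uch <- chars[i0:(i0 + m - 1L)]
      # template: position j matches iff chars[j] == uch[((j - i0) mod m) + 1]
      tmatch <- function(j) valid[j] && chars[j] == uch[((j - i0) %% m) + 1L]
      s <- i0
      e <- rends[k] + m
      mc <- e - s + 1L            # seed region is an exact template match
      # extend right
      streak <- 0L
      while (e < L && streak < 2L) {
        j <- e + 1L
        if (!valid[j]) break
        ok <- tmatch(j)
        if ((mc + ok) / (j - s + 1L) < minp) break
        e <- j
        mc <- mc + ok
        streak <- if (ok) 0L else streak + 1L
      }
      # extend left
      streak <- 0L
      while (s > 1L && streak < 2L) {
        j <- s - 1L
        if (!valid[j]) break
        ok <- tmatch(j)
        if ((mc + ok) / (e - j + 1L) < minp) break
        s <- j
        mc <- mc + ok
        streak <- if (ok) 0L else streak + 1L
      }
      # trim terminal mismatches
      while (e >= s && !tmatch(e)) e <- e - 1L
      while (s <= e && !tmatch(s)) s <- s + 1L
      len <- e - s + 1L
      if (len < config$min_locus_length) next
      nr <- nr + 1L
      rows[[nr]] <- list(chrom = chrom, start = s - 1L, end = e,
                         unit = unit, m = m)
    }
  }
  if (nr == 0L) return(NULL)
  df <- data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
                   start = vapply(rows, `[[`, 0L, "start"),
                   end = vapply(rows, `[[`, 0L, "end"),
                   unit = vapply(rows, `[[`, "", "unit"),
                   m = vapply(rows, `[[`, 0L, "m"),
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df[c("start", "end", "unit")]), , drop = FALSE]
  df$motif <- canonical_motif(df$unit)
  df$ref_length <- df$end - df$start
  df$copies <- df$ref_length / df$m
  df$purity <- mapply(function(s, e, u) {
    compute_purity(substr(seqstr, s + 1L, e), u)
  }, df$start, df$end, df$unit)
  # same interval reachable from different units: keep shortest motif,
  # then highest purity, then lexicographically smallest motif
  df <- df[order(df$start, df$end, df$m, -df$purity, df$motif), , drop = FALSE]
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  df[c("chrom", "start", "end", "motif", "copies", "purity", "ref_length")]
}

#' Filter and deduplicate catalogue candidates
#'
#' Applies the locus filters (length, motif copies, purity) and resolves
#' overlapping candidates to a single survivor: higher purity wins, then
#' greater length, then leftmost start. The result is sorted by
#' (chrom, start) and carries a `locus_id` column.
#'
#' @param candidates Data frame from [scan_tandem_repeats()].
#' @param config A [catalogue_config()].
#' @return Filtered catalogue data frame with pairwise disjoint loci.
#' @export
filter_and_dedupe <- function(candidates, config = catalogue_config()) {
  df <- candidates
  if (is.null(df) || nrow(df) == 0L) {
    out <- .empty_catalogue()
    out$locus_id <- character(0)
    return(out)
  }
  if (is.null(df$ref_length)) df$ref_length <- df$end - df$start
  keep <- df$ref_length >= config$min_locus_length &
    df$copies >= config$min_motif_copies &
    df$purity >= config$min_purity
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0L) {
    out <- .empty_catalogue()
    out$locus_id <- character(0)
    return(out)
  }
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  hits <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  off <- q != s
  adj <- split(s[off], q[off])
  ord <- order(-df$purity, -df$ref_length, df$chrom, df$start)
  selected <- logical(nrow(df))
  blocked <- logical(nrow(df))
  for (i in ord) {
    if (blocked[i]) next
    selected[i] <- TRUE
    nb <- adj[[as.character(i)]]
    if (!is.null(nb)) blocked[nb] <- TRUE
  }
  df <- df[selected, , drop = FALSE]
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  df$locus_id <- sprintf("%s_%d_%d", df$chrom, df$start, df$end)
  rownames(df) <- NULL
  df
}

#' Build a filtered microsatellite catalogue from a reference
#'
#' Convenience wrapper: [scan_tandem_repeats()] followed by
#' [filter_and_dedupe()].
#'
#' @inheritParams scan_tandem_repeats
#' @return Filtered catalogue data frame.
#' @export
build_catalogue <- function(reference, config = catalogue_config()) {
  filter_and_dedupe(scan_tandem_repeats(reference, config), config)
}

#' Write a catalogue to TSV
#'
#' Tab-separated with header; the first three columns are
#' `chrom`, `start`, `end` (0-based half-open), so the file doubles as
#' BED3+ for interval tools. `copies` and `purity` are written with 17
#' significant digits so that the write/read round trip is lossless.
#'
#' @param catalogue Catalogue data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalogue <- function(catalogue, path) {
  df <- catalogue
  if (is.null(df$locus_id)) {
    df$locus_id <- sprintf("%s_%d_%d", df$chrom, df$start, df$end)
  }
  df <- df[c("chrom", "start", "end", "motif", "copies", "purity", "locus_id")]
  df$copies <- sprintf("%.17g", df$copies)
  df$purity <- sprintf("%.17g", df$purity)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a catalogue TSV
#'
#' @param path Path written by [write_catalogue()] (or any TSV with the same
#'   columns; 1-based inclusive `start` coordinates from TRF-style exports
#'   can be converted with `one_based = TRUE`).
#' @param one_based Set TRUE when `start` is 1-based inclusive; it is
#'   converted to the internal 0-based half-open convention.
#' @return Catalogue data frame.
#' @export
read_catalogue <- function(path, one_based = FALSE) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = c(chrom = "character",
                                         start = "integer", end = "integer",
                                         motif = "character",
                                         copies = "numeric",
                                         purity = "numeric",
                                         locus_id = "character"))
  if (one_based) df$start <- df$start - 1L
  df$ref_length <- df$end - df$start
  df[c("chrom", "start", "end", "motif", "copies", "purity",
       "ref_length", "locus_id")]
}

#' Sample non-MST control loci
#'
#' Draws `n` fixed-length segments uniformly over the mappable reference
#' (no ambiguity codes), excluding any segment that overlaps a catalogue
#' locus. Matched control loci make the somatic-variation statistics of
#' repeat loci comparable to non-repeat DNA.
#'
#' @param reference Reference sequences.
#' @param catalogue Filtered catalogue data frame (may be empty).
#' @param n Number of segments to draw.
#' @param seed Integer seed; the same seed reproduces the same segments.
#' @param config A [catalogue_config()] supplying the segment length.
#' @return Data frame `chrom`, `start`, `end`, `locus_id`. If fewer than `n`
#'   placements exist, the shorter list is returned with a warning.
#' @export
sample_non_mst_loci <- function(reference, catalogue, n, seed,
                                config = catalogue_config()) {
  stopifnot(n >= 1L)
  reference <- load_reference(reference)
  w <- config$non_mst_segment_length
  pools <- lapply(names(reference), function(chrom) {
    seqstr <- reference[[chrom]]
    L <- nchar(seqstr)
    if (L < w) return(NULL)
    chars <- strsplit(seqstr, "", fixed = TRUE)[[1L]]
    bad <- !(chars == "A" | chars == "C" | chars == "G" | chars == "T")
    cov <- logical(L)
    cat_c <- catalogue[catalogue$chrom == chrom, , drop = FALSE]
    if (nrow(cat_c)) {
      for (i in seq_len(nrow(cat_c))) {
        cov[(cat_c$start[i] + 1L):cat_c$end[i]] <- TRUE
      }
    }
    block <- bad | cov
    cs <- c(0L, cumsum(block))
    starts1 <- seq_len(L - w + 1L)
    ok <- (cs[starts1 + w] - cs[starts1]) == 0L
    if (!any(ok)) return(NULL)
    data.frame(chrom = chrom, start = starts1[ok] - 1L,
               stringsAsFactors = FALSE)
  })
  pool <- do.call(rbind, pools)
  if (is.null(pool) || nrow(pool) == 0L) {
    warning("no non-MST segments can be placed on this reference")
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), locus_id = character(0),
                      stringsAsFactors = FALSE))
  }
  if (nrow(pool) < n) {
    warning(sprintf("only %d of %d requested non-MST segments can be placed",
                    nrow(pool), n))
    idx <- seq_len(nrow(pool))
  } else {
    set.seed(seed)
    idx <- sample.int(nrow(pool), n)
  }
  out <- pool[idx, , drop = FALSE]
  out$end <- out$start + w
  out$locus_id <- sprintf("NMS_%s_%d_%d", out$chrom, out$start, out$end)
  rownames(out) <- NULL
  out[c("chrom", "start", "end", "locus_id")]
}
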