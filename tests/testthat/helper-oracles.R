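# Independent reference implementations used as oracles. These transcribe
# the documented semantics with deliberately different code (explicit
# per-position loops, environments as hash maps) and share no internals
# with the package.

oracle_rotations <- function(m) {
  n <- nchar(m)
  out <- character(n)
  for (k in 0:(n - 1L)) {
    out[k + 1L] <- paste0(substring(m, k + 1L, n), substring(m, 1L, k))
  }
  out
}

oracle_purity <- function(s, motif) {
  L <- nchar(s)
  sc <- strsplit(s, "")[[1L]]
  best <- 0
  for (rot in oracle_rotations(motif)) {
    rc <- strsplit(rot, "")[[1L]]
    hits <- 0L
    for (i in seq_len(L)) {
      if (sc[i] == rc[((i - 1L) %% length(rc)) + 1L]) hits <- hits + 1L
    }
    best <- max(best, hits / L)
  }
  best
}

oracle_primitive <- function(u) {
  n <- nchar(u)
  if (n == 1L) return(TRUE)
  for (d in 1:(n - 1L)) {
    if (n %% d == 0L) {
      if (paste(rep(substring(u, 1L, d), n / d), collapse = "") == u) {
        return(FALSE)
      }
    }
  }
  TRUE
}

oracle_canonical <- function(u) {
  rots <- oracle_rotations(u)
  rots[order(rots)][1L]
}

# Candidate detector semantics, independent transcription: exact-core
# seeds (>= 2 copies and >= max(2m, 4) nt), greedy right-then-left
# extension under the seed's periodic template while the match fraction
# stays >= min_purity and fewer than 2 consecutive terminal mismatches
# accumulate, then terminal-mismatch trimming.
oracle_scan <- function(seqstr, min_purity = 0.85, min_len = 8L) {
  chars <- strsplit(seqstr, "")[[1L]]
  L <- length(chars)
  valid <- chars %in% c("A", "C", "G", "T")
  rows <- list()
  for (m in 1:6) {
    if (L < 2L * m) next
    i <- 1L
    while (i + m <= L) {
      if (valid[i] && valid[i + m] && chars[i] == chars[i + m]) {
        j <- i
        while (j + m <= L && valid[j] && valid[j + m] &&
                 chars[j] == chars[j + m]) {
          j <- j + 1L
        }
        runlen <- j - i
        if (runlen >= max(m, 4L - m)) {
          unit <- paste(chars[i:(i + m - 1L)], collapse = "")
          if (oracle_primitive(unit)) {
            anchor <- i
            tm <- function(p) {
              valid[p] && chars[p] == chars[anchor + ((p - anchor) %% m)]
            }
            s <- i
            e <- i + runlen + m - 1L
            mc <- e - s + 1L
            streak <- 0L
            while (e < L && streak < 2L) {
              ok <- tm(e + 1L)
              if (!valid[e + 1L]) break
              if ((mc + ok) / (e + 1L - s + 1L) < min_purity) break
              e <- e + 1L
              mc <- mc + ok
              streak <- if (ok) 0L else streak + 1L
            }
            streak <- 0L
            while (s > 1L && streak < 2L) {
              ok <- tm(s - 1L)
              if (!valid[s - 1L]) break
              if ((mc + ok) / (e - (s - 1L) + 1L) < min_purity) break
              s <- s - 1L
              mc <- mc + ok
              streak <- if (ok) 0L else streak + 1L
            }
            while (e >= s && !tm(e)) e <- e - 1L
            while (s <= e && !tm(s)) s <- s + 1L
            if (e - s + 1L >= min_len) {
              rows[[length(rows) + 1L]] <-
                list(start = s - 1L, end = e, unit = unit, m = m)
            }
          }
        }
        i <- j + 1L
      } else {
        i <- i + 1L
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      motif = character(0)))
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  df <- df[!duplicated(df[c("start", "end", "unit")]), , drop = FALSE]
  df$purity <- mapply(function(s, e, u) {
    oracle_purity(substring(seqstr, s + 1L, e), u)
  }, df$start, df$end, df$unit)
  df$motif <- vapply(df$unit, oracle_canonical, "")
  # same interval from several units: shortest motif, highest purity,
  # smallest motif
  df <- df[order(df$start, df$end, df$m, -df$purity, df$motif), , drop = FALSE]
  df <- df[!duplicated(df[c("start", "end")]), , drop = FALSE]
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  df[c("start", "end", "motif", "purity")]
}

# Exhaustive transcription of the allele tally + locus-call rules using an
# environment as a hash map.
oracle_call <- function(obs, depth, min_reads = 3L, both_strand = TRUE,
                        min_depth = 15L, het_total = 0.25, het_major = 0.5) {
  env <- new.env()
  if (!is.null(obs) && nrow(obs)) {
    for (r in seq_len(nrow(obs))) {
      key <- obs$allele_seq[r]
      v <- if (exists(key, envir = env, inherits = FALSE))
        get(key, envir = env) else c(f = 0L, r = 0L)
      if (obs$strand[r] == "+") v["f"] <- v["f"] + 1L else v["r"] <- v["r"] + 1L
      assign(key, v, envir = env)
    }
  }
  called <- list()
  for (key in ls(env)) {
    v <- get(key, envir = env)
    tot <- v[["f"]] + v[["r"]]
    ok <- tot >= min_reads
    if (both_strand) ok <- ok && v[["f"]] >= 1L && v[["r"]] >= 1L
    if (ok) {
      called[[length(called) + 1L]] <-
        data.frame(allele_seq = key, n_forward = v[["f"]],
                   n_reverse = v[["r"]], n_total = tot,
                   stringsAsFactors = FALSE)
    }
  }
  al <- if (length(called)) do.call(rbind, called) else
    data.frame(allele_seq = character(0), n_forward = integer(0),
               n_reverse = integer(0), n_total = integer(0))
  al <- al[order(-al$n_total, -nchar(al$allele_seq), al$allele_seq), ,
           drop = FALSE]
  rownames(al) <- NULL
  if (depth < min_depth) {
    return(list(zygosity = "uncalled", alleles = al, n_hap = 0L))
  }
  if (nrow(al) == 0L) {
    return(list(zygosity = "uncalled", alleles = al, n_hap = 0L))
  }
  het <- FALSE
  if (nrow(al) >= 2L) {
    total_called <- sum(al$n_total)
    het <- al$n_total[2L] > het_total * total_called ||
      al$n_total[2L] > het_major * al$n_total[1L]
  }
  list(zygosity = if (het) "heterozygous" else "homozygous",
       alleles = al, n_hap = if (het) 2L else 1L)
}

# Brute-force interval intersection count between two 0-based half-open
# interval sets on named chromosomes.
oracle_n_overlaps <- function(a, b) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
            a$start[i] < b$end[j] && b$start[j] < a$end[i]) {
        n <- n + 1L
      }
    }
  }
  n
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
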