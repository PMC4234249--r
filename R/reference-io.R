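# Reference sequence handling. Internally a reference is a named character
# vector of uppercase sequences; FASTA files go through Biostrings.

#' Load a reference sequence set
#'
#' Accepts a FASTA path, a `Biostrings::DNAStringSet`, or a named character
#' vector, and returns a named uppercase character vector of sequences.
#'
#' @param reference FASTA file path, `DNAStringSet`, or named character vector.
#' @return Named character vector of uppercase sequences.
#' @export
load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- as.character(reference)
    # FASTA headers often carry descriptions after the first token
    names(out) <- sub("\\s.*$", "", names(reference))
    return(toupper(out))
  }
  if (is.character(reference)) {
    if (is.null(names(reference)) || any(!nzchar(names(reference)))) {
      stop("character reference must be named by sequence", call. = FALSE)
    }
    return(toupper(reference))
  }
  stop("unsupported reference type: ", class(reference)[1L], call. = FALSE)
}

#' Write a reference to FASTA
#'
#' @param reference Named character vector or `DNAStringSet`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  reference <- load_reference(reference)
  dss <- Biostrings::DNAStringSet(reference)
  Biostrings::writeXStringSet(dss, filepath = path)
  invisible(path)
}
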