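#' Read a reference sequence from FASTA
#'
#' Loads a FASTA file into a `DNAStringSet` with upper-case bases. Sequence
#' names are truncated at the first whitespace, matching the convention of
#' most aligners and variant callers.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) {
    stop("reference FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

# Coerce user-supplied reference-like input (DNAStringSet, named character
# vector, or FASTA path) to a DNAStringSet.
as_reference <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    return(genome)
  }
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    return(read_reference(genome))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  stop("`genome` must be a DNAStringSet, a named character vector, ",
       "or a FASTA file path", call. = FALSE)
}

#' Extract fixed-width sequence windows around positions
#'
#' For each 1-based position, returns the window `[pos - up, pos + down]` from
#' the named sequence. Windows that run outside `[1, length]` are returned as
#' `NA` (the caller decides whether that is an error or an exclusion).
#'
#' @param genome A [Biostrings::DNAStringSet] (or coercible input).
#' @param chrom Character vector of sequence names.
#' @param pos Integer vector of 1-based positions.
#' @param up,down Number of bases to include 5' and 3' of `pos`.
#' @return Character vector of windows (length `up + down + 1`), `NA` where
#'   out of bounds.
#' @export
seq_context <- function(genome, chrom, pos, up = 1L, down = 1L) {
  genome <- as_reference(genome)
  stopifnot(length(chrom) == length(pos))
  out <- rep(NA_character_, length(pos))
  unknown <- !chrom %in% names(genome)
  if (any(unknown)) {
    stop("unknown sequence name(s): ",
         paste(unique(chrom[unknown]), collapse = ", "), call. = FALSE)
  }
  for (cn in unique(chrom)) {
    idx <- which(chrom == cn)
    s <- genome[[cn]]
    len <- length(s)
    start <- pos[idx] - up
    end <- pos[idx] + down
    ok <- start >= 1L & end <= len
    if (any(ok)) {
      windows <- Biostrings::extractAt(
        s, IRanges::IRanges(start = start[ok], end = end[ok])
      )
      out[idx[ok]] <- as.character(windows)
    }
  }
  out
}
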