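#' @keywords internal
#' @importFrom rlang .data
#' @import tibble
"_PACKAGE"

## Canonical single-base-substitution alphabet -------------------------------

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DNA_BASES <- c("A", "C", "G", "T")

#' Canonical 96-channel labels
#'
#' Returns the 96 trinucleotide-context substitution channels in the canonical
#' order used by public SBS signature releases: the six pyrimidine-strand
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G, each with its 16 flanking
#' contexts sorted alphabetically by 5' then 3' base. Labels use the bracket
#' notation `A[C>A]A`.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' head(sbs_channels())
sbs_channels <- function() {
  unlist(lapply(SBS_CLASSES, function(cls) {
    as.vector(t(outer(DNA_BASES, DNA_BASES, function(f, t) {
      paste0(f, "[", cls, "]", t)
    })))
  }), use.names = FALSE)
}

# Decompose channel labels into (five_prime, ref, alt, three_prime).
channel_parts <- function(channels = sbs_channels()) {
  tibble::tibble(
    channel = channels,
    five_prime = substr(channels, 1L, 1L),
    pyr_ref = substr(channels, 3L, 3L),
    pyr_alt = substr(channels, 5L, 5L),
    three_prime = substr(channels, 7L, 7L),
    class = paste0(substr(channels, 3L, 3L), ">", substr(channels, 5L, 5L))
  )
}

# Complement of a base vector; anything outside ACGT maps to N.
complement_base <- function(x) {
  out <- chartr("ACGTacgt", "TGCATGCA", x)
  out[!out %in% DNA_BASES] <- "N"
  out
}

# Vectorised reverse complement of equal-purpose short strings.
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_pyrimidine <- function(x) x %in% c("C", "T")
is_purine <- function(x) x %in% c("A", "G")
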