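#' @keywords internal
"_PACKAGE"

#' @importFrom Biostrings DNAStringSet reverseComplement readDNAStringSet
#'   writeXStringSet
#' @importFrom stats loess predict rpois rbinom runif rnorm quantile median
#'   cor.test t.test p.adjust sd setNames approx
#' @importFrom utils read.delim write.table head
NULL

DNA_BASES <- c("A", "C", "G", "T")

## Fixed amplicon anchors flanking (arm + barcode); used by the read
## simulator and by the read filters ("wrong start and end").
ANCHOR_5P <- "ACACTCTTTCCC"
ANCHOR_3P <- "AGATCGGAAGAG"

#' Validate and normalize a nucleotide sequence
#'
#' Accepts DNA or RNA alphabet, upper- or lower-case; returns an upper-case
#' DNA-alphabet string (U mapped to T).
#'
#' @param x A single character string.
#' @param what Label used in error messages.
#' @return Normalized sequence string.
#' @keywords internal
normalize_seq <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(what, " must be a single character string")
  }
  s <- chartr("u", "t", x)
  s <- toupper(s)
  s <- chartr("U", "T", s)
  if (nchar(s) > 0L && grepl("[^ACGT]", s)) {
    bad <- unique(strsplit(gsub("[ACGT]", "", s), "")[[1]])
    stop(what, " contains invalid characters: ", paste(bad, collapse = ", "))
  }
  s
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp("GGGG")
revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Positions of adenosines in a sequence
#'
#' @param x A sequence string.
#' @return Integer vector of 0-based positions of `A`.
#' @export
adenosine_positions <- function(x) {
  which(seq_chars(normalize_seq(x)) == "A") - 1L
}
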