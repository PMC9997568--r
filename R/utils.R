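IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement a DNA string
#'
#' IUPAC ambiguity codes are complemented to their degenerate counterparts.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

is_iupac <- function(x) {
  grepl("^[ACGTRYSWKMBDHVN]+$", x)
}

is_dna <- function(x) {
  grepl("^[ACGTN]+$", x)
}

#' Translate a coding sequence
#'
#' Translates the leading complete codons of `cds`; a trailing partial codon
#' is ignored. Stop codons appear as `*`.
#'
#' @param cds a DNA string (character scalar).
#' @return amino-acid string.
#' @export
translate_dna <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  n <- (nchar(cds) %/% 3L) * 3L
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substr(cds, 1L, n)),
    if.fuzzy.codon = "X", no.init.codon = TRUE
  ))
}

# premature (internal) stop in a translated protein?
has_internal_stop <- function(protein) {
  if (nchar(protein) <= 1L) return(FALSE)
  grepl("\\*", substr(protein, 1L, nchar(protein) - 1L))
}

# stable seed derivation for sub-streams, kept under 2^31
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset) * 7919L) %% 2147483587L
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
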