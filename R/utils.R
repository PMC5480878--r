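## Shared sequence helpers. All coordinates in memory are 1-based closed
## intervals (R convention); on-disk interchange formats convert where noted.

DNA_BASES <- c("A", "C", "G", "T")

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse-complement nucleotide strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' accepts and returns plain character vectors (IUPAC codes, including `N`,
#' are handled).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "AANT"))
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Translate nucleotide sequences
#'
#' Translates in the standard genetic code starting at `frame_start`
#' (1-based). Codons containing `N` (or any non-ACGT letter) translate to
#' `"X"` and are never treated as stop codons; a trailing partial codon is
#' dropped.
#'
#' @param x Character vector of nucleotide sequences.
#' @param frame_start 1-based position of the first codon.
#' @return Character vector of amino-acid strings (`*` marks stops).
#' @export
#' @examples
#' translate_nt("ATGGCTTAA")
translate_nt <- function(x, frame_start = 1L) {
  code <- Biostrings::GENETIC_CODE
  vapply(x, function(s) {
    s <- substr(s, frame_start, nchar(s))
    n <- nchar(s) %/% 3L
    if (n == 0L) return("")
    codons <- substring(s, 3L * (seq_len(n) - 1L) + 1L, 3L * seq_len(n))
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## One codon per amino acid, used when the simulator engineers a specific
## amino-acid replacement.
AA_CODON <- c(
  A = "GCT", R = "AGA", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGA", H = "CAT", I = "ATT", L = "CTG", K = "AAA",
  M = "ATG", F = "TTC", P = "CCT", S = "AGC", T = "ACA", W = "TGG",
  Y = "TAC", V = "GTT"
)

#' Hamming distance between equal-length strings
#'
#' @param a,b Character vectors (recycled) of equal-length strings.
#' @return Integer vector of mismatch counts.
#' @export
hamming <- function(a, b) {
  stopifnot(all(nchar(a) == nchar(b)))
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}

## Random DNA of given length (no constraint on stops).
random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

## Random in-frame codon stretch free of stop codons.
random_codons <- function(n_codons) {
  all_codons <- apply(expand.grid(DNA_BASES, DNA_BASES, DNA_BASES), 1, paste, collapse = "")
  ok <- setdiff(all_codons, STOP_CODONS)
  paste(sample(ok, n_codons, replace = TRUE), collapse = "")
}

## Replace characters at `pos` (1-based) of string `s` with `base`.
str_assign <- function(s, pos, base) {
  ch <- strsplit(s, "")[[1]]
  ch[pos] <- base
  paste(ch, collapse = "")
}

## Phred+33 quality string helpers.
phred_to_char <- function(q) intToUtf8(q + 33L, multiple = FALSE)

min_phred <- function(qual) {
  vapply(qual, function(s) {
    if (nchar(s) == 0L) return(NA_integer_)
    min(utf8ToInt(s)) - 33L
  }, integer(1), USE.NAMES = FALSE)
}

## Derive a bounded child seed from a master seed and a stage offset.
child_seed <- function(seed, k) {
  (as.integer(seed) * 7919L + as.integer(k) * 104729L) %% 2147483587L
}
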