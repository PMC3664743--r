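# small shared helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A/C/G/T (IUPAC letters allowed)
#' @return the reverse complement as a character scalar
#' @export
revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# round half away from zero, the convention used by the printed tables
roundHalfUp <- function(x, digits = 0L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# "n (p.p)" cell formatting used in the report tables
formatCountPct <- function(n, pct) sprintf("%d (%.1f)", n, pct)

#' Normalize an allele name to the package's canonical ASCII spelling
#'
#' Accepts the Unicode prime character (U+2032) and the "p" ASCII alias
#' (e.g. "GmF3pH" -> "GmF3'H").
#'
#' @param x character vector of allele or locus names
#' @return canonicalized character vector
#' @export
normalizeAlleleName <- function(x) {
  x <- gsub("\u2032", "'", x)
  x <- gsub("3p", "3'", x, fixed = TRUE)
  gsub("5p", "5'", x, fixed = TRUE)
}

randomDnaString <- function(n, gc = 0.5) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

# all in-frame codons of a CDS string
splitCodons <- function(x) {
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return(character())
  substring(x, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
}
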