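#' The eight co-occurrence pattern sets
#'
#' Returns the named list of row-pattern vectors defining the eight
#' co-occurrence matrices I..P. Matrix I pairs single bases with the
#' following base (the classical dinucleotide matrix); J uses the four
#' homo-dinucleotides; K the six ordered hetero-dinucleotides and L their
#' reversals; M..P partition a family of trinucleotide patterns. In every
#' matrix the column alphabet is A, C, T, G: cell (r, s) counts occurrences
#' of row pattern r immediately followed by base s.
#'
#' @return Named list of character vectors; names are "I".."P".
#' @examples
#' coocPatternSets()$I   # "A" "C" "T" "G"
#' lengths(coocPatternSets())
#' @export
coocPatternSets <- function() {
  list(
    I = c("A", "C", "T", "G"),
    J = c("AA", "CC", "TT", "GG"),
    K = c("AC", "AT", "AG", "CT", "CG", "TG"),
    L = c("CA", "TA", "GA", "TC", "GC", "GT"),
    M = c("ACT", "ACG", "ATG", "CTG"),
    N = c("CAT", "CAG", "TAG", "TCG"),
    O = c("ATC", "AGC", "AGT", "CGT"),
    P = c("TCA", "GCA", "GTA", "GTC")
  )
}

#' Column alphabet of the co-occurrence matrices
#'
#' @return Character vector c("A", "C", "T", "G").
#' @export
coocColAlphabet <- function() BASES
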