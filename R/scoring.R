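#' BLOSUM62-based alignment scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' statistics used throughout the package. BLOSUM62 entries are half-bit
#' integers; penalties follow the BLAST convention, where a gap of length L
#' costs `|gap_open| + (L - 1) * |gap_extend|`.
#'
#' @param gap_open Gap-opening penalty applied to the first gap residue
#'   (default -11, as in BLASTP).
#' @param gap_extend Penalty per additional gap residue (default -1).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters for gapped
#'   BLOSUM62(11,1) raw scores, used by [compute_evalue()].
#' @return A list of class `scoring_scheme` with elements `matrix`,
#'   `gap_open`, `gap_extend`, `karlin_lambda`, `karlin_k`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(gap_open = -11, gap_extend = -1,
                           karlin_lambda = 0.267, karlin_k = 0.041) {
  if (gap_open > 0 || gap_extend > 0) {
    abort("gap penalties must be given as non-positive numbers")
  }
  structure(
    list(
      matrix = blosum62(),
      gap_open = gap_open,
      gap_extend = gap_extend,
      karlin_lambda = karlin_lambda,
      karlin_k = karlin_k
    ),
    class = "scoring_scheme"
  )
}

#' The BLOSUM62 substitution matrix
#'
#' Returned as an integer matrix in half-bit units, from Biostrings.
#'
#' @return A symmetric numeric matrix over the amino-acid alphabet
#'   (20 standard residues plus ambiguity codes).
#' @export
blosum62 <- function() {
  if (is.null(.phamr$blosum62)) {
    e <- new.env()
    data("BLOSUM62", package = "Biostrings", envir = e)
    .phamr$blosum62 <- e$BLOSUM62
  }
  .phamr$blosum62
}

# the 20 standard residues in the conventional order
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' BLOSUM62 background amino-acid frequencies
#'
#' Robinson-Robinson style background frequencies associated with BLOSUM62,
#' used as priors when building position-specific scoring profiles and when
#' sampling synthetic protein sequences.
#'
#' @return A named numeric vector over the 20 standard residues, summing to 1.
#' @export
blosum62_background <- function() {
  p <- c(
    A = 0.0742, R = 0.0516, N = 0.0446, D = 0.0536, C = 0.0246,
    Q = 0.0342, E = 0.0543, G = 0.0741, H = 0.0262, I = 0.0679,
    L = 0.0989, K = 0.0582, M = 0.0221, F = 0.0474, P = 0.0390,
    S = 0.0577, T = 0.0509, W = 0.0130, Y = 0.0321, V = 0.0729
  )
  p / sum(p)
}
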