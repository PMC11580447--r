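#' Canonical amino-acid alphabet
#'
#' The 20 canonical one-letter amino-acid codes, in the fixed order used by
#' every emission/background vector in the package. \code{"X"} is tolerated in
#' sequences as an unknown residue but is never part of this alphabet.
#'
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids()
aminoAcids <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

#' Background amino-acid frequencies
#'
#' Average composition of proteins (Swiss-Prot style averages), used as the
#' default null model for profile-HMM log-odds scoring, for pseudocount
#' mixing, and as the base measure for decoy-sequence generation.
#'
#' @return Named numeric vector over [aminoAcids()], summing to 1.
#' @export
#' @examples
#' sum(backgroundFrequencies())
backgroundFrequencies <- function() {
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93,
         E = 6.75, G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84,
         M = 2.42, F = 3.86, P = 4.70, S = 6.56, T = 5.34, W = 1.08,
         Y = 2.92, V = 6.87)
  f <- f[aminoAcids()]
  f / sum(f)
}

#' Kyte-Doolittle hydropathy scale
#'
#' @return Named numeric vector of per-residue hydropathy values over the 20
#'   canonical amino acids (range -4.5 for Arg to +4.5 for Ile).
#' @export
#' @examples
#' kyteDoolittle()[["I"]]
kyteDoolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)[aminoAcids()]
}

#' Average residue masses
#'
#' Average (not monoisotopic) masses of amino-acid residues in a peptide
#' chain, in daltons. A free peptide adds one water ([waterMass()]).
#'
#' @return Named numeric vector in Da.
#' @export
residueMasses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760,
    V = 99.1326)[aminoAcids()]
}

#' @rdname residueMasses
#' @export
waterMass <- function() 18.0153

#' EMBOSS pK table
#'
#' The pK values of the EMBOSS scale used for Henderson-Hasselbalch net-charge
#' and isoelectric-point calculations. Stored as data so that an alternative
#' scale can be passed to [netCharge()] and [isoelectricPoint()].
#'
#' @return Named numeric vector with entries \code{Nterm}, \code{Cterm} and
#'   the ionizable side chains \code{K}, \code{R}, \code{H} (basic) and
#'   \code{D}, \code{E}, \code{C}, \code{Y} (acidic).
#' @export
#' @examples
#' embossPk()[["K"]]
embossPk <- function() {
  c(Nterm = 8.6, Cterm = 3.6,
    K = 10.8, R = 12.5, H = 6.5,
    D = 3.9, E = 4.1, C = 8.5, Y = 10.1)
}

# Internal: map residue characters to 0-based alphabet indices (X and other
# unknowns -> NA) for the C++ kernels.
aaIndex <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, aminoAcids()) - 1L
}

# Internal: single sequence string from an AAStringSet element or character.
asSequenceString <- function(x) {
  if (is(x, "XStringSet")) {
    stopifnot(length(x) == 1L)
    return(as.character(x[[1L]]))
  }
  if (is(x, "XString")) return(as.character(x))
  stopifnot(is.character(x), length(x) == 1L)
  x
}
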