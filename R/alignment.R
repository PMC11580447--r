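#' @useDynLib aureomine, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.pkgCache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.pkgCache$BLOSUM62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .pkgCache$BLOSUM62 <- e$BLOSUM62
  }
  .pkgCache$BLOSUM62
}

#' Construct an alignment scoring scheme
#'
#' @param matrixName Substitution matrix name; \code{"BLOSUM62"} (the default)
#'   is loaded from Biostrings.
#' @param gapOpen Penalty for the first position of a gap (default -10).
#' @param gapExtend Penalty per additional gap position (default -1).
#' @param substitution Optional explicit symmetric substitution matrix with
#'   residue dimnames, overriding \code{matrixName}.
#' @return A [ScoringScheme-class] object.
#' @export
#' @examples
#' scoringScheme()
scoringScheme <- function(matrixName = "BLOSUM62", gapOpen = -10,
                          gapExtend = -1, substitution = NULL) {
  if (is.null(substitution)) {
    if (matrixName != "BLOSUM62")
      stop("only BLOSUM62 is packaged; pass `substitution` for other matrices")
    substitution <- blosum62()
  }
  new("ScoringScheme", matrixName = matrixName, substitution = substitution,
      gapOpen = gapOpen, gapExtend = gapExtend)
}

subIndices <- function(seq, scheme) {
  rows <- rownames(scheme@substitution)
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], rows) - 1L
  if (anyNA(idx))
    stop("residue not covered by the substitution matrix in: ", seq)
  idx
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch global alignment under a [ScoringScheme-class]
#' (Gotoh three-state recursion). A gap of length L costs
#' \code{gapOpen + (L - 1) * gapExtend}. Traceback ties are broken
#' deterministically: diagonal over up (gap in \code{b}) over left (gap in
#' \code{a}), so the returned alignment is a pure function of its inputs.
#'
#' @param a,b Sequences: single-element AAStringSet, AAString, or character
#'   scalar (optionally named).
#' @param scheme A [ScoringScheme-class]; default [scoringScheme()].
#' @return A [GlobalAlignment-class].
#' @export
#' @examples
#' aln <- globalAlign("MKWLT", "MKLT")
#' percentIdentity(aln)
globalAlign <- function(a, b, scheme = scoringScheme()) {
  idA <- if (!is.null(names(a)) && nzchar(names(a)[1L])) names(a)[1L] else "seqA"
  idB <- if (!is.null(names(b)) && nzchar(names(b)[1L])) names(b)[1L] else "seqB"
  sa <- asSequenceString(a); sb <- asSequenceString(b)
  if (!nzchar(sa) || !nzchar(sb)) stop("cannot align an empty sequence")
  res <- .nw_align(subIndices(sa, scheme), subIndices(sb, scheme),
                   scheme@substitution, scheme@gapOpen, scheme@gapExtend)
  ca <- strsplit(sa, "", fixed = TRUE)[[1L]]
  cb <- strsplit(sb, "", fixed = TRUE)[[1L]]
  colA <- ifelse(res$a > 0L, ca[pmax(res$a, 1L)], "-")
  colB <- ifelse(res$b > 0L, cb[pmax(res$b, 1L)], "-")
  nId <- sum(colA == colB & colA != "-")
  new("GlobalAlignment", alignedA = paste(colA, collapse = ""),
      alignedB = paste(colB, collapse = ""), idA = idA, idB = idB,
      score = res$score, nIdentical = as.integer(nId),
      nColumns = length(colA))
}

#' Percent identity of a global alignment
#'
#' Identity convention: identical non-gap columns over *total alignment
#' columns* (gaps included in the denominator), reported to 0.01 precision.
#' Under this convention 14 identical residues in a 52-column alignment give
#' 26.92 (displayed as 26.9).
#'
#' @param aln A [GlobalAlignment-class].
#' @return Percent identity in [0, 100].
#' @export
percentIdentity <- function(aln) {
  stopifnot(is(aln, "GlobalAlignment"))
  round(100 * aln@nIdentical / aln@nColumns, 2)
}

# Merge two gapped renderings of the same ungapped sequence into the union
# gap pattern ("once a gap, always a gap"). Returns per-union-column flags of
# which input rendering consumes a column.
mergeGapPatterns <- function(c1, c2) {
  x1 <- strsplit(c1, "", fixed = TRUE)[[1L]]
  x2 <- strsplit(c2, "", fixed = TRUE)[[1L]]
  i1 <- 1L; i2 <- 1L; n1 <- length(x1); n2 <- length(x2)
  take1 <- logical(0); take2 <- logical(0)
  while (i1 <= n1 || i2 <= n2) {
    r1 <- i1 <= n1 && x1[i1] != "-"
    r2 <- i2 <= n2 && x2[i2] != "-"
    if (r1 && r2) {
      take1 <- c(take1, TRUE); take2 <- c(take2, TRUE); i1 <- i1 + 1L; i2 <- i2 + 1L
    } else if (i1 <= n1 && !r1) {
      take1 <- c(take1, TRUE); take2 <- c(take2, FALSE); i1 <- i1 + 1L
    } else {
      take1 <- c(take1, FALSE); take2 <- c(take2, TRUE); i2 <- i2 + 1L
    }
  }
  list(take1 = take1, take2 = take2)
}

expandRow <- function(row, take) {
  out <- rep("-", length(take))
  out[take] <- strsplit(row, "", fixed = TRUE)[[1L]]
  paste(out, collapse = "")
}

#' Star-progressive multiple sequence alignment
#'
#' A fully defined, deterministic MSA: the center sequence is the one with
#' the highest summed pairwise alignment score to all others (ties: first in
#' input order); every other sequence is aligned to the center pairwise, and
#' center gap patterns are merged under the "once a gap, always a gap" rule.
#' Row order follows the input.
#'
#' @param records AAStringSet of >= 2 sequences.
#' @param scheme A [ScoringScheme-class].
#' @return AAStringSet of equal-width gapped rows, named as the input.
#' @export
starMsa <- function(records, scheme = scoringScheme()) {
  n <- length(records)
  if (n < 2L) stop("star MSA needs at least 2 sequences")
  seqs <- as.character(records)
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  scores <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    aln <- globalAlign(seqs[i], seqs[j], scheme)
    scores[i, j] <- scores[j, i] <- aln@score
  }
  center <- which.max(rowSums(scores))
  cRow <- seqs[center]                 # master center rendering
  rows <- vector("list", n); rows[[center]] <- seqs[center]
  for (j in setdiff(seq_len(n), center)) {
    aln <- globalAlign(seqs[center], seqs[j], scheme)
    mg <- mergeGapPatterns(cRow, aln@alignedA)
    # expand all existing rows to the union pattern
    for (k in seq_len(n)) {
      if (!is.null(rows[[k]])) rows[[k]] <- expandRow(rows[[k]], mg$take1)
    }
    cRow <- rows[[center]]
    rows[[j]] <- expandRow(aln@alignedB, mg$take2)
  }
  out <- AAStringSet(unlist(rows[seq_len(n)]))
  names(out) <- ids
  out
}
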