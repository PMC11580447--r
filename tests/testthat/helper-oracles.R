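# Independent oracles used across the suite. These deliberately share no
# code with the package implementation: paths are enumerated explicitly,
# alignments are enumerated column by column, and p-values come from label
# permutations.

# Sum of odds over ALL explicit glocal state paths of a profile HMM, by
# depth-first enumeration. Returns the log2-odds forward score.
oracleForward <- function(hmm, seq, best = FALSE) {
  M <- hmm@modelLength
  bg <- hmm@background
  tr <- hmm@transitions
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1L]], aminoAcids())
  L <- length(idx)
  mOdds <- function(k, i) if (is.na(idx[i])) 1 else
    hmm@matchEmissions[k, idx[i]] / bg[idx[i]]
  iOdds <- function(k, i) if (is.na(idx[i])) 1 else
    hmm@insertEmissions[k + 1L, idx[i]] / bg[idx[i]]
  acc <- if (best) max else sum

  # odds of completing the sequence from state (type, node) with i residues
  # already emitted
  rec <- function(type, k, i) {
    out <- numeric(0)
    row <- k + 1L
    if (type == "M" || type == "B") {
      if (k == M) {
        if (i == L) out <- c(out, tr[row, "MM"])
      } else {
        if (i < L) out <- c(out, tr[row, "MM"] * mOdds(k + 1L, i + 1L) *
                              rec("M", k + 1L, i + 1L))
        out <- c(out, tr[row, "MD"] * rec("D", k + 1L, i))
      }
      if (i < L) out <- c(out, tr[row, "MI"] * iOdds(k, i + 1L) *
                            rec("I", k, i + 1L))
    } else if (type == "I") {
      if (k == M) {
        if (i == L) out <- c(out, tr[row, "IM"])
      } else if (i < L) {
        out <- c(out, tr[row, "IM"] * mOdds(k + 1L, i + 1L) *
                   rec("M", k + 1L, i + 1L))
      }
      if (i < L) out <- c(out, tr[row, "II"] * iOdds(k, i + 1L) *
                            rec("I", k, i + 1L))
    } else { # D
      if (k == M) {
        if (i == L) out <- c(out, tr[row, "DM"])
      } else {
        if (i < L) out <- c(out, tr[row, "DM"] * mOdds(k + 1L, i + 1L) *
                              rec("M", k + 1L, i + 1L))
        out <- c(out, tr[row, "DD"] * rec("D", k + 1L, i))
      }
    }
    if (length(out)) acc(out) else 0
  }
  log2(rec("B", 0L, 0L))
}

oracleViterbi <- function(hmm, seq) oracleForward(hmm, seq, best = TRUE)

# random small profile HMM for oracle batteries (valid by construction)
randomToyHmm <- function(M, alphaEm = 0.5) {
  bg <- backgroundFrequencies()
  rdir <- function(alpha) { x <- stats::rgamma(length(alpha), alpha); x / sum(x) }
  matchEm <- t(vapply(seq_len(M), function(k) rdir(rep(alphaEm, 20)),
                      numeric(20L)))
  insertEm <- t(vapply(seq_len(M + 1L), function(k) rdir(bg * 40),
                       numeric(20L)))
  colnames(matchEm) <- colnames(insertEm) <- aminoAcids()
  tr <- matrix(0, M + 1L, 7L,
               dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II", "DM", "DD")))
  for (k in seq_len(M + 1L)) {
    mdAllowed <- k <= M
    x <- rdir(rep(2, if (mdAllowed) 3 else 2))
    tr[k, c("MM", "MI", if (mdAllowed) "MD")] <- x
    y <- rdir(rep(2, 2)); tr[k, c("IM", "II")] <- y
    if (k == 1L || !mdAllowed) tr[k, "DM"] <- 1 else {
      z <- rdir(rep(2, 2)); tr[k, c("DM", "DD")] <- z
    }
  }
  new("ProfileHMM", modelLength = as.integer(M), matchEmissions = matchEm,
      insertEmissions = insertEm, transitions = tr, background = unname(bg),
      pseudocountWeight = 0, matchColumns = seq_len(M))
}

randomPeptide <- function(L, prob = backgroundFrequencies()) {
  paste(sample(aminoAcids(), L, replace = TRUE, prob = prob), collapse = "")
}

# Brute-force optimal global affine alignment score by enumerating every
# alignment (gap of length L costs open + (L - 1) * extend).
oracleAlignScore <- function(a, b, scheme = scoringScheme()) {
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sub <- scheme@substitution
  open <- scheme@gapOpen; ext <- scheme@gapExtend
  best <- -Inf
  # state: i, j consumed; score so far; last column type (0 none, 1 gap in
  # b, 2 gap in a) to price gap runs
  rec <- function(i, j, sc, last) {
    if (i == length(ca) && j == length(cb)) {
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < length(ca) && j < length(cb))
      rec(i + 1L, j + 1L, sc + sub[ca[i + 1L], cb[j + 1L]], 0L)
    if (i < length(ca))
      rec(i + 1L, j, sc + if (last == 1L) ext else open, 1L)
    if (j < length(cb))
      rec(i, j + 1L, sc + if (last == 2L) ext else open, 2L)
  }
  rec(0L, 0L, 0, 0L)
  best
}

# Exact permutation p-value for a two-group Kruskal-Wallis test: every
# reassignment of group labels, P(H >= H_obs).
oracleKwPermutation <- function(x, y) {
  vals <- c(x, y)
  n <- length(vals); n1 <- length(x)
  Hof <- function(idx) {
    r <- rank(vals)
    R1 <- mean(r[idx]); R2 <- mean(r[-idx])
    ties <- table(vals)
    corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
    (12 / (n * (n + 1)) * (n1 * R1^2 + (n - n1) * R2^2) - 3 * (n + 1)) / corr
  }
  obs <- Hof(seq_len(n1))
  combos <- utils::combn(n, n1)
  hs <- apply(combos, 2L, Hof)
  mean(hs >= obs - 1e-12)
}

# additive distance matrix from a random unrooted tree (via ape, which is
# independent of the package's NJ implementation)
randomAdditiveMatrix <- function(nTaxa) {
  tr <- ape::rtree(nTaxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  ids <- sort(rownames(dm))
  list(tree = tr, dm = dm[ids, ids])
}

expect_valid_fasta_roundtrip <- function(records) {
  f <- withr::local_tempfile(fileext = ".faa")
  writeFasta(records, f)
  back <- readFasta(f)
  expect_identical(as.character(back), as.character(records))
  expect_identical(names(back), names(records))
}
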