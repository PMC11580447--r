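#' Build a profile HMM from a seed alignment
#'
#' Estimates a match/insert/delete profile HMM from an aligned set of core
#' peptides. Columns whose gap fraction is strictly below
#' \code{occupancyThreshold} become match states (a column at exactly the
#' threshold becomes insert); emissions are background-mixture pseudocount
#' estimates, \code{(frequency + w * background) / (1 + w)}; transitions are
#' counted from the observed state path of every row and Laplace-smoothed
#' (+1 on every legal transition) before normalization.
#'
#' @param msa Aligned sequences (AAStringSet or character vector), all of
#'   equal length, gaps as \code{"-"}; at least 2 rows.
#' @param occupancyThreshold Gap-fraction cutoff for match columns
#'   (default 0.5; strictly-less rule).
#' @param pseudocountWeight Background-mixture weight w >= 0 (default 1).
#' @param background Null amino-acid frequencies (default
#'   [backgroundFrequencies()]).
#' @return A [ProfileHMM-class].
#' @export
#' @examples
#' hmm <- buildHmm(c(a = "MKW", b = "MKW"))
#' hmm
buildHmm <- function(msa, occupancyThreshold = 0.5, pseudocountWeight = 1,
                     background = backgroundFrequencies()) {
  rows <- if (is(msa, "XStringSet")) as.character(msa) else msa
  if (length(rows) < 2L) stop("alignment needs at least 2 rows")
  if (length(unique(nchar(rows))) != 1L)
    stop("ragged alignment: rows differ in length")
  aa <- aminoAcids()
  chars <- do.call(rbind, strsplit(toupper(rows), "", fixed = TRUE))
  ncolA <- ncol(chars)
  gapFrac <- colMeans(chars == "-")
  isMatch <- gapFrac < occupancyThreshold
  M <- sum(isMatch)
  if (M == 0L) stop("alignment has zero match columns at this threshold")
  nodeOfCol <- cumsum(isMatch)           # node index after consuming column

  mixEmission <- function(counts) {
    tot <- sum(counts)
    freq <- if (tot > 0) counts / tot else background
    (freq + pseudocountWeight * background) / (1 + pseudocountWeight)
  }

  matchEm <- matrix(0, M, 20L, dimnames = list(NULL, aa))
  mcols <- which(isMatch)
  for (k in seq_len(M)) {
    counts <- table(factor(chars[, mcols[k]], levels = aa))
    matchEm[k, ] <- mixEmission(as.numeric(counts))
  }

  insertEm <- matrix(0, M + 1L, 20L, dimnames = list(NULL, aa))
  icols <- which(!isMatch)
  for (k in 0L:M) {
    cc <- icols[nodeOfCol[icols] == k]
    counts <- if (length(cc))
      as.numeric(table(factor(chars[, cc], levels = aa))) else numeric(20L)
    insertEm[k + 1L, ] <- mixEmission(counts)
  }

  # transition counts from per-row state paths (B = node 0 "M"; exit to E
  # recorded in the node-M MM/IM/DM slots)
  slots <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")
  counts <- matrix(0, M + 1L, 7L, dimnames = list(NULL, slots))
  for (r in seq_len(nrow(chars))) {
    prevType <- "M"; prevNode <- 0L
    for (c in seq_len(ncolA)) {
      res <- chars[r, c] != "-"
      if (isMatch[c]) {
        type <- if (res) "M" else "D"
        node <- nodeOfCol[c]
      } else if (res) {
        type <- "I"; node <- nodeOfCol[c]
      } else next
      slot <- paste0(prevType, type)
      # D->I and I->D adjacencies have no edge in the plan-7-style
      # architecture; such pairs are skipped rather than counted
      if (slot %in% slots)
        counts[prevNode + 1L, slot] <- counts[prevNode + 1L, slot] + 1
      prevType <- type; prevNode <- node
    }
    counts[M + 1L, paste0(prevType, "M")] <- counts[M + 1L, paste0(prevType, "M")] + 1
  }

  legal <- matrix(TRUE, M + 1L, 7L, dimnames = list(NULL, slots))
  legal[M + 1L, c("MD", "DD")] <- FALSE      # no D_{M+1}
  trans <- matrix(0, M + 1L, 7L, dimnames = list(NULL, slots))
  bundles <- list(c("MM", "MI", "MD"), c("IM", "II"), c("DM", "DD"))
  for (k in seq_len(M + 1L)) {
    for (b in bundles) {
      ok <- b[legal[k, b]]
      if (k == 1L && identical(b, bundles[[3L]])) { # begin node has no D source
        trans[k, "DM"] <- 1
        next
      }
      v <- counts[k, ok] + 1
      trans[k, ok] <- v / sum(v)
    }
  }

  new("ProfileHMM", modelLength = as.integer(M), matchEmissions = matchEm,
      insertEmissions = insertEm, transitions = trans,
      background = unname(background),
      pseudocountWeight = pseudocountWeight,
      matchColumns = as.integer(mcols))
}

# log-odds tables consumed by the C++ kernels
hmmTables <- function(hmm) {
  bg <- hmm@background
  list(lm = log2(sweep(hmm@matchEmissions, 2L, bg, "/")),
       li = log2(sweep(hmm@insertEmissions, 2L, bg, "/")),
       ltr = log2(hmm@transitions))
}

seqToIdx <- function(seq) {
  idx <- aaIndex(asSequenceString(seq))
  idx[is.na(idx)] <- -1L
  idx
}

#' Glocal forward bit score
#'
#' log2 of P(sequence | model) / P(sequence | background), summed over all
#' glocal paths (whole model against whole sequence) by the forward recursion
#' in log space. \code{X} residues emit at background frequency (odds 1) in
#' every state.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seqs An AAStringSet (scored element-wise) or a single sequence.
#' @return Numeric vector of bit scores.
#' @export
forwardScore <- function(hmm, seqs) {
  tb <- hmmTables(hmm)
  if (is(seqs, "XStringSet")) {
    if (any(width(seqs) < 1L)) stop("cannot score an empty sequence")
    vapply(as.character(seqs),
           function(s) .phmm_forward(tb$lm, tb$li, tb$ltr, seqToIdx(s)),
           numeric(1L), USE.NAMES = !is.null(names(seqs)))
  } else {
    s <- asSequenceString(seqs)
    if (!nzchar(s)) stop("cannot score an empty sequence")
    .phmm_forward(tb$lm, tb$li, tb$ltr, seqToIdx(s))
  }
}

#' Viterbi alignment to a profile HMM
#'
#' Maximum-scoring glocal state path. Ties between predecessor states are
#' broken by the fixed priority M < D < I. The Viterbi bit score is never
#' above the forward score.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seq A single sequence.
#' @return List with \code{score} (bits), \code{path} (matrix of state type
#'   0=M/1=D/2=I, node, 1-based emitted position or 0), and
#'   \code{matchRow}: the sequence rendered over the M match states (residue
#'   for match, \code{"-"} for delete), used to extend the seed alignment.
#' @export
viterbiAlign <- function(hmm, seq) {
  tb <- hmmTables(hmm)
  s <- asSequenceString(seq)
  if (!nzchar(s)) stop("cannot align an empty sequence")
  res <- .phmm_viterbi(tb$lm, tb$li, tb$ltr, seqToIdx(s))
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  matchRow <- ifelse(res$matchTrace > 0L, chars[pmax(res$matchTrace, 1L)], "-")
  list(score = res$score, path = res$path,
       matchRow = paste(matchRow, collapse = ""))
}

#' Calibrate the score null of a profile HMM
#'
#' Scores \code{nNull} i.i.d. background sequences with the forward
#' algorithm. Two fits are produced. The method-of-moments Gumbel,
#' \code{lambda = pi / (sd * sqrt(6))}, \code{mu = mean - gamma / lambda}
#' (gamma the Euler-Mascheroni constant), is always computed. The default
#' \code{method = "tail"} additionally fits the exceedances over the
#' empirical \code{1 - tailFraction} quantile with a Weibull
#' (stretched-exponential) law by maximum likelihood; glocal forward null
#' scores decay faster than a Gumbel, and the tail fit keeps E-values
#' calibrated in the small-E regime where the discovery gate operates (see
#' the methods vignette). Null sequence lengths are drawn with replacement
#' from \code{seqLengths} so the null matches the length distribution of the
#' database being searched.
#'
#' @param hmm A [ProfileHMM-class].
#' @param dbComposition Residue frequencies the nulls are drawn from
#'   (typically the empirical database composition).
#' @param nNull Number of null sequences (>= 100).
#' @param seqLengths Integer vector of target lengths to resample.
#' @param method "tail" (default) or "moments".
#' @param tailFraction Upper-tail fraction for the peaks-over-threshold fit.
#' @return A [NullCalibration-class].
#' @export
calibrateNull <- function(hmm, dbComposition = backgroundFrequencies(),
                          nNull = 1000L, seqLengths = 60L,
                          method = c("tail", "moments"),
                          tailFraction = 0.1) {
  method <- match.arg(method)
  if (nNull < 100L) stop("calibration needs nNull >= 100")
  pool <- as.integer(seqLengths)
  lens <- pool[sample.int(length(pool), nNull, replace = TRUE)]
  tb <- hmmTables(hmm)
  scores <- vapply(seq_len(nNull), function(i) {
    idx <- sample.int(20L, lens[i], replace = TRUE, prob = dbComposition) - 1L
    .phmm_forward(tb$lm, tb$li, tb$ltr, idx)
  }, numeric(1L))
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) stop("null scores have zero variance")
  lambda <- pi / (s * sqrt(6))
  gamma <- 0.57721566490153286
  mu <- mean(scores) - gamma / lambda

  tau <- sig <- k <- NA_real_
  if (method == "tail") {
    tau <- unname(stats::quantile(scores, 1 - tailFraction))
    ex <- scores[scores > tau] - tau
    ex <- ex[ex > 0]
    if (length(ex) < 20L)
      stop("too few tail exceedances; increase nNull or tailFraction")
    fit <- weibullTailFit(ex)
    sig <- fit[["sigma"]]; k <- fit[["k"]]
  }
  new("NullCalibration", method = method, gumbelMu = mu,
      gumbelLambda = lambda, tailTau = tau,
      tailQ = if (method == "tail") tailFraction else NA_real_,
      tailSigma = sig, tailK = k, nNull = as.integer(nNull))
}

# Weibull MLE on positive exceedances (survival exp(-(x/sigma)^k))
weibullTailFit <- function(x) {
  nll <- function(p) {
    k <- exp(p[1L]); sig <- exp(p[2L])
    -sum(log(k) - log(sig) + (k - 1) * (log(x) - log(sig)) - (x / sig)^k)
  }
  o <- stats::optim(c(0, log(mean(x))), nll)
  c(k = exp(o$par[1L]), sigma = exp(o$par[2L]))
}

nullSurvival <- function(cal, bitScore) {
  gum <- 1 - exp(-exp(-cal@gumbelLambda * (bitScore - cal@gumbelMu)))
  if (cal@method == "moments") return(gum)
  p <- ifelse(bitScore > cal@tailTau,
              cal@tailQ * exp(-((bitScore - cal@tailTau) / cal@tailSigma)^
                                cal@tailK),
              # below the threshold, rescale the Gumbel bulk so the two
              # pieces meet continuously at tau (strictly monotone)
              cal@tailQ * gum /
                (1 - exp(-exp(-cal@gumbelLambda *
                                (cal@tailTau - cal@gumbelMu)))))
  pmin(1, p)
}

#' E-value of a bit score under the calibrated null
#'
#' The expected number of null sequences scoring at or above the query in a
#' database of the stated size: \code{E = dbSize * P(null >= score)}. For a
#' moments calibration this is the closed Gumbel form
#' \code{dbSize * (1 - exp(-exp(-lambda * (score - mu))))}; for a tail
#' calibration the Weibull peaks-over-threshold survival is used above the
#' tail threshold, with the Gumbel bulk rescaled to meet it continuously
#' below. E-values are monotone decreasing in the bit score.
#'
#' @param cal A [NullCalibration-class].
#' @param bitScore Numeric vector of forward bit scores.
#' @param dbSize Number of sequences searched.
#' @return E-values (same length as \code{bitScore}).
#' @export
evalue <- function(cal, bitScore, dbSize) {
  stopifnot(is(cal, "NullCalibration"))
  dbSize * nullSurvival(cal, bitScore)
}

#' Two-round iterative profile-HMM mining
#'
#' The discovery loop: the database is restricted to proteins strictly under
#' \code{maxLen} residues; a model built from the seed alignment is
#' calibrated on shuffled-composition nulls and used to score the filtered
#' database; hits below the E-value threshold are aligned back to the model
#' by Viterbi, appended to the alignment (over its match columns), and the
#' rebuilt model is recalibrated and searched again. The union of hits is
#' reported with the iteration of first discovery.
#'
#' @param seedMsa Aligned seed core peptides (AAStringSet or character).
#' @param db AAStringSet database to mine.
#' @param eThreshold E-value gate (default 1e-5).
#' @param maxLen Length filter: only proteins with fewer residues are
#'   searched (default 100, strict).
#' @param nIterations 1 or 2 (default 2).
#' @param calibrationN Null sequences per calibration (default 1000).
#' @param occupancyThreshold,pseudocountWeight Passed to [buildHmm()].
#' @return data.frame with columns \code{sequence_id}, \code{bit_score},
#'   \code{e_value}, \code{iteration}, ordered by decreasing bit score.
#'   Scores are those of the round in which the hit was first found.
#' @export
iterativeSearch <- function(seedMsa, db, eThreshold = 1e-5, maxLen = 100L,
                            nIterations = 2L, calibrationN = 1000L,
                            occupancyThreshold = 0.5, pseudocountWeight = 1) {
  rows <- if (is(seedMsa, "XStringSet")) as.character(seedMsa) else seedMsa
  if (!length(rows)) stop("empty seed alignment")
  emptyHits <- data.frame(sequence_id = character(0), bit_score = numeric(0),
                          e_value = numeric(0), iteration = integer(0))
  keep <- width(db) < maxLen
  filtered <- db[keep]
  if (!length(filtered)) {
    warning("no database sequences under the length filter")
    return(emptyHits)
  }
  comp <- empiricalComposition(filtered)
  dbSize <- length(filtered)

  hmm <- buildHmm(rows, occupancyThreshold, pseudocountWeight)
  cal <- calibrateNull(hmm, comp, calibrationN, width(filtered))
  sc <- forwardScore(hmm, filtered)
  ev <- evalue(cal, sc, dbSize)
  found <- ev < eThreshold
  hits <- data.frame(sequence_id = names(filtered)[found],
                     bit_score = unname(sc[found]),
                     e_value = unname(ev[found]),
                     iteration = rep(1L, sum(found)))

  if (nIterations >= 2L && nrow(hits)) {
    seedCore <- vapply(strsplit(rows, "", fixed = TRUE), function(ch)
      paste(ch[hmm@matchColumns], collapse = ""), character(1L))
    hitRows <- vapply(hits$sequence_id, function(id)
      viterbiAlign(hmm, filtered[id])$matchRow, character(1L))
    hmm2 <- buildHmm(c(seedCore, unname(hitRows)), occupancyThreshold,
                     pseudocountWeight)
    cal2 <- calibrateNull(hmm2, comp, calibrationN, width(filtered))
    sc2 <- forwardScore(hmm2, filtered)
    ev2 <- evalue(cal2, sc2, dbSize)
    new2 <- ev2 < eThreshold & !(names(filtered) %in% hits$sequence_id)
    if (any(new2)) {
      hits <- rbind(hits, data.frame(sequence_id = names(filtered)[new2],
                                     bit_score = unname(sc2[new2]),
                                     e_value = unname(ev2[new2]),
                                     iteration = rep(2L, sum(new2))))
    }
  }
  hits[order(-hits$bit_score, hits$sequence_id), , drop = FALSE]
}

#' Empirical amino-acid composition of a sequence set
#'
#' @param db AAStringSet.
#' @return Named frequency vector over [aminoAcids()] (X ignored), smoothed
#'   by one pseudo-observation per residue so no frequency is exactly zero.
#' @export
empiricalComposition <- function(db) {
  chars <- strsplit(paste(as.character(db), collapse = ""), "", fixed = TRUE)[[1L]]
  counts <- table(factor(chars, levels = aminoAcids()))
  f <- as.numeric(counts) + 1
  stats::setNames(f / sum(f), aminoAcids())
}

#' Serialize a profile HMM as versioned plain text
#'
#' A simple documented text format: a version header, model dimensions,
#' background, match-column map, then one row per state table entry at full
#' double precision. [readProfileHmm()] restores an identical model.
#'
#' @param hmm A [ProfileHMM-class].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeProfileHmm <- function(hmm, path) {
  fm <- function(x) paste(formatC(x, format = "g", digits = 17), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("aureomine-profile-hmm 1",
               paste("M", hmm@modelLength),
               paste("PC", fm(hmm@pseudocountWeight)),
               paste("BG", fm(hmm@background)),
               paste("MATCHCOLS", paste(hmm@matchColumns, collapse = " "))),
             con)
  for (k in seq_len(hmm@modelLength))
    writeLines(paste("MATCH", k, fm(hmm@matchEmissions[k, ])), con)
  for (k in 0L:hmm@modelLength)
    writeLines(paste("INSERT", k, fm(hmm@insertEmissions[k + 1L, ])), con)
  for (k in 0L:hmm@modelLength)
    writeLines(paste("TRANS", k, fm(hmm@transitions[k + 1L, ])), con)
  invisible(path)
}

#' @rdname writeProfileHmm
#' @export
readProfileHmm <- function(path) {
  lines <- readLines(path)
  if (!grepl("^aureomine-profile-hmm 1$", lines[1L]))
    stop("not an aureomine profile HMM file (or unsupported version)")
  fields <- strsplit(lines[-1L], " +")
  tag <- vapply(fields, `[`, character(1L), 1L)
  num <- function(f, from) as.numeric(f[-seq_len(from)])
  M <- as.integer(fields[[which(tag == "M")]][2L])
  pc <- as.numeric(fields[[which(tag == "PC")]][2L])
  bg <- num(fields[[which(tag == "BG")]], 1L)
  mc <- as.integer(fields[[which(tag == "MATCHCOLS")]][-1L])
  aa <- aminoAcids()
  matchEm <- matrix(0, M, 20L, dimnames = list(NULL, aa))
  insertEm <- matrix(0, M + 1L, 20L, dimnames = list(NULL, aa))
  trans <- matrix(0, M + 1L, 7L,
                  dimnames = list(NULL, c("MM", "MI", "MD", "IM", "II",
                                          "DM", "DD")))
  for (f in fields[tag == "MATCH"])
    matchEm[as.integer(f[2L]), ] <- num(f, 2L)
  for (f in fields[tag == "INSERT"])
    insertEm[as.integer(f[2L]) + 1L, ] <- num(f, 2L)
  for (f in fields[tag == "TRANS"])
    trans[as.integer(f[2L]) + 1L, ] <- num(f, 2L)
  new("ProfileHMM", modelLength = M, matchEmissions = matchEm,
      insertEmissions = insertEm, transitions = trans, background = bg,
      pseudocountWeight = pc, matchColumns = mc)
}
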