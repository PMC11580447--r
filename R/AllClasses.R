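#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

#' Scoring scheme for global peptide alignment
#'
#' Bundles a symmetric substitution matrix with affine gap penalties. The gap
#' convention is open + (L - 1) * extend for a gap of length L (the first gap
#' position pays the opening penalty).
#'
#' @slot matrixName Name of the substitution matrix (default BLOSUM62).
#' @slot substitution Symmetric numeric substitution matrix with residue
#'   dimnames.
#' @slot gapOpen Negative penalty for the first position of a gap.
#' @slot gapExtend Negative penalty for each further gap position, with
#'   \code{abs(gapExtend) <= abs(gapOpen)}.
#' @export
setClass("ScoringScheme",
  representation(matrixName = "character", substitution = "matrix",
                 gapOpen = "numeric", gapExtend = "numeric"))

setValidity("ScoringScheme", function(object) {
  m <- object@substitution
  if (!isTRUE(all.equal(m, t(m)))) return("substitution matrix not symmetric")
  if (object@gapOpen > 0 || object@gapExtend > 0)
    return("gap penalties must be <= 0")
  if (abs(object@gapExtend) > abs(object@gapOpen))
    return("|gapExtend| must be <= |gapOpen|")
  TRUE
})

#' Global pairwise peptide alignment
#'
#' Result of [globalAlign()]: two gapped strings of equal length, the affine
#' alignment score, and identity bookkeeping used by [percentIdentity()].
#'
#' @slot alignedA,alignedB Equal-length aligned strings over residues and
#'   \code{"-"}.
#' @slot idA,idB Sequence identifiers.
#' @slot score Optimal affine Needleman-Wunsch score.
#' @slot nIdentical Count of columns with equal non-gap residues.
#' @slot nColumns Alignment length.
#' @export
setClass("GlobalAlignment",
  representation(alignedA = "character", alignedB = "character",
                 idA = "character", idB = "character",
                 score = "numeric", nIdentical = "integer",
                 nColumns = "integer"))

setValidity("GlobalAlignment", function(object) {
  if (nchar(object@alignedA) != nchar(object@alignedB))
    return("aligned strings differ in length")
  if (nchar(object@alignedA) != object@nColumns)
    return("nColumns inconsistent with aligned strings")
  la <- nchar(gsub("-", "", object@alignedA, fixed = TRUE))
  lb <- nchar(gsub("-", "", object@alignedB, fixed = TRUE))
  if (object@nIdentical > min(la, lb))
    return("nIdentical exceeds min sequence length")
  TRUE
})

setMethod("show", "GlobalAlignment", function(object) {
  cat("GlobalAlignment: ", object@idA, " vs ", object@idB, "\n", sep = "")
  cat("  score ", format(object@score), ", ", object@nIdentical, "/",
      object@nColumns, " identical (", format(
        round(100 * object@nIdentical / object@nColumns, 2)), "%)\n", sep = "")
  cat("  ", object@alignedA, "\n  ", object@alignedB, "\n", sep = "")
})

#' Profile hidden Markov model for core-peptide families
#'
#' Match/insert/delete architecture estimated from a seed alignment by
#' [buildHmm()]. Emission rows and per-node transition bundles are proper
#' probability distributions; scoring is glocal (whole model against whole
#' sequence) in log2-odds against \code{background}.
#'
#' @slot modelLength Number of match states M (>= 1).
#' @slot matchEmissions M x 20 matrix of match-state emission probabilities.
#' @slot insertEmissions (M + 1) x 20 matrix of insert-state emissions for
#'   insert states I0..IM.
#' @slot transitions (M + 1) x 7 matrix of per-node transition probabilities
#'   with columns MM, MI, MD, IM, II, DM, DD. Row 1 is the begin node (B->M1,
#'   B->I0, B->D1); in the last row MM, IM and DM are the exits to the end
#'   state.
#' @slot background Length-20 null frequencies.
#' @slot pseudocountWeight Nonnegative background-mixture pseudocount weight.
#' @slot matchColumns Which columns of the source alignment became match
#'   states.
#' @export
setClass("ProfileHMM",
  representation(modelLength = "integer", matchEmissions = "matrix",
                 insertEmissions = "matrix", transitions = "matrix",
                 background = "numeric", pseudocountWeight = "numeric",
                 matchColumns = "integer"))

setValidity("ProfileHMM", function(object) {
  M <- object@modelLength
  if (M < 1L) return("model must have at least one match state")
  if (nrow(object@matchEmissions) != M) return("matchEmissions must have M rows")
  if (nrow(object@insertEmissions) != M + 1L)
    return("insertEmissions must have M + 1 rows")
  if (nrow(object@transitions) != M + 1L || ncol(object@transitions) != 7L)
    return("transitions must be (M + 1) x 7")
  tol <- 1e-9
  if (any(abs(rowSums(object@matchEmissions) - 1) > tol))
    return("match emission rows must sum to 1")
  if (any(abs(rowSums(object@insertEmissions) - 1) > tol))
    return("insert emission rows must sum to 1")
  tr <- object@transitions
  bundles <- cbind(rowSums(tr[, c("MM", "MI", "MD")]),
                   rowSums(tr[, c("IM", "II")]),
                   rowSums(tr[, c("DM", "DD")]))
  if (any(abs(bundles - 1) > tol))
    return("each transition bundle (M*, I*, D*) must sum to 1")
  if (abs(sum(object@background) - 1) > tol)
    return("background must sum to 1")
  if (object@pseudocountWeight < 0) return("pseudocountWeight must be >= 0")
  TRUE
})

setMethod("show", "ProfileHMM", function(object) {
  cons <- paste(aminoAcids()[apply(object@matchEmissions, 1L, which.max)],
                collapse = "")
  cat("ProfileHMM with ", object@modelLength, " match states\n", sep = "")
  cat("  consensus: ", cons, "\n", sep = "")
  cat("  pseudocount weight: ", object@pseudocountWeight, "\n", sep = "")
})

#' Null calibration of forward bit scores
#'
#' Converts bit scores to E-values ([evalue()]) from forward scores of
#' shuffled-composition null sequences. Two fits are stored: a Gumbel law
#' fitted by the method of moments (location \code{gumbelMu}, scale
#' \code{gumbelLambda}), and — for \code{method = "tail"} — a
#' stretched-exponential (Weibull) peaks-over-threshold fit of the upper
#' tail, \code{P(S >= tailTau + x) = tailQ * exp(-(x / tailSigma)^tailK)},
#' which tracks the lighter-than-Gumbel decay of glocal forward scores.
#'
#' @slot method "tail" or "moments" — which fit [evalue()] uses.
#' @slot gumbelMu Gumbel location, in bits (method of moments).
#' @slot gumbelLambda Gumbel scale parameter (1/bits), positive.
#' @slot tailTau Tail threshold (empirical 1 - tailQ quantile), bits.
#' @slot tailQ Tail fraction used for the peaks-over-threshold fit.
#' @slot tailSigma,tailK Weibull scale and shape of the exceedance law.
#' @slot nNull Number of null sequences scored (>= 100).
#' @export
setClass("NullCalibration",
  representation(method = "character", gumbelMu = "numeric",
                 gumbelLambda = "numeric", tailTau = "numeric",
                 tailQ = "numeric", tailSigma = "numeric", tailK = "numeric",
                 nNull = "integer"))

setValidity("NullCalibration", function(object) {
  if (!object@method %in% c("tail", "moments"))
    return("method must be 'tail' or 'moments'")
  if (object@gumbelLambda <= 0) return("gumbelLambda must be positive")
  if (object@method == "tail" &&
      (object@tailSigma <= 0 || object@tailK <= 0 ||
       object@tailQ <= 0 || object@tailQ >= 1))
    return("tail fit requires sigma > 0, k > 0 and q in (0, 1)")
  if (object@nNull < 100L) return("calibration needs at least 100 null sequences")
  TRUE
})

setMethod("show", "NullCalibration", function(object) {
  cat("NullCalibration (", object@method, ") from ", object@nNull,
      " null sequences\n", sep = "")
  cat("  Gumbel MoM: mu = ", format(object@gumbelMu, digits = 4),
      ", lambda = ", format(object@gumbelLambda, digits = 4), "\n", sep = "")
  if (object@method == "tail")
    cat("  tail: tau = ", format(object@tailTau, digits = 4),
        ", sigma = ", format(object@tailSigma, digits = 4),
        ", k = ", format(object@tailK, digits = 3),
        " (top ", 100 * object@tailQ, "%)\n", sep = "")
})

#' Sequence similarity network of core peptides
#'
#' Nodes are peptide ids, edges connect pairs whose global percent identity is
#' strictly above the threshold; connected components define peptide groups
#' and degree-zero nodes are singletons.
#'
#' @slot nodes data.frame with columns id, phylum, component, degree.
#' @slot edges data.frame with columns source, target, pid (each unordered
#'   pair once).
#' @slot threshold Edge threshold in percent identity.
#' @export
setClass("Ssn",
  representation(nodes = "data.frame", edges = "data.frame",
                 threshold = "numeric"))

setValidity("Ssn", function(object) {
  need <- c("id", "phylum", "component", "degree")
  if (!all(need %in% names(object@nodes)))
    return("nodes must have id, phylum, component, degree")
  if (nrow(object@edges) &&
      !all(c("source", "target", "pid") %in% names(object@edges)))
    return("edges must have source, target, pid")
  if (anyDuplicated(object@nodes$id)) return("duplicate node ids")
  sing <- object@nodes$degree == 0L
  comp <- object@nodes$component
  if (any(table(comp[!sing]) < 2L))
    return("non-singleton components must have >= 2 members")
  TRUE
})

setMethod("show", "Ssn", function(object) {
  cat("Ssn: ", nrow(object@nodes), " peptides, ", nrow(object@edges),
      " edges at > ", object@threshold, "% identity\n", sep = "")
  cat("  components: ", length(unique(object@nodes$component)),
      " (", sum(object@nodes$degree == 0L), " singletons)\n", sep = "")
})

#' Greedy identity clusters (CD-HIT style)
#'
#' @slot clusters data.frame with columns representative, member; every input
#'   id appears exactly once as a member and each member has percent identity
#'   to its representative at or above the threshold.
#' @slot threshold Identity threshold as a fraction in (0, 1].
#' @export
setClass("ClusterSet",
  representation(clusters = "data.frame", threshold = "numeric"))

setValidity("ClusterSet", function(object) {
  if (!all(c("representative", "member") %in% names(object@clusters)))
    return("clusters must have representative and member columns")
  if (anyDuplicated(object@clusters$member))
    return("each id must be a member of exactly one cluster")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must be in (0, 1]")
  TRUE
})

setMethod("show", "ClusterSet", function(object) {
  reps <- unique(object@clusters$representative)
  cat("ClusterSet: ", nrow(object@clusters), " peptides in ", length(reps),
      " clusters at ", 100 * object@threshold, "% identity\n", sep = "")
})

#' Bacteriocin gene cluster neighborhood
#'
#' The annotated window around one or more core-peptide genes, with each CDS
#' assigned a functional role and operon-architecture flags.
#'
#' @slot contig Contig identifier.
#' @slot coreGeneIds Ids of the core-peptide genes in the window (>= 1).
#' @slot features GRanges of window CDS with mcols gene_id, product, role.
#' @slot nCore Number of core genes.
#' @slot flags Named logical vector: has_transport, has_membrane,
#'   has_regulator, contig_edge, opposite_strand_machinery,
#'   functional_operon.
#' @slot category "single" or "multi".
#' @slot window Integer window bounds (start, end) after clipping to the
#'   contig.
#' @export
setClass("Bgc",
  representation(contig = "character", coreGeneIds = "character",
                 features = "GRanges", nCore = "integer",
                 flags = "logical", category = "character",
                 window = "integer"))

setValidity("Bgc", function(object) {
  if (object@nCore < 1L) return("a BGC needs at least one core gene")
  if (object@category != ifelse(object@nCore >= 2L, "multi", "single"))
    return("category must be multi iff nCore >= 2")
  need <- c("has_transport", "has_membrane", "has_regulator", "contig_edge",
            "opposite_strand_machinery", "functional_operon")
  if (!all(need %in% names(object@flags))) return("missing flags")
  if (length(object@features) &&
      (min(GenomicRanges::start(object@features)) < object@window[1L] ||
       max(GenomicRanges::end(object@features)) > object@window[2L])) {
    # features overlap the window; they may extend past it only partially
    ov <- GenomicRanges::start(object@features) <= object@window[2L] &
      GenomicRanges::end(object@features) >= object@window[1L]
    if (!all(ov)) return("features must overlap the window")
  }
  TRUE
})

setMethod("show", "Bgc", function(object) {
  cat("Bgc on ", object@contig, " [", object@window[1L], "-",
      object@window[2L], "]: ", object@nCore, " core peptide(s), ",
      object@category, "\n", sep = "")
  on <- names(object@flags)[object@flags]
  cat("  flags: ", if (length(on)) paste(on, collapse = ", ") else "none",
      "\n", sep = "")
})

#' Synthetic-data configuration
#'
#' Parameters of the synthetic protein database, taxonomy and operon layouts
#' emitted by [generateProteinDb()] and [simulateStudy()]. Defaults are the
#' package's standard study conditions; see the methods vignette.
#'
#' @slot seedPeptide AAStringSet of length 1: the family seed (~50 aa,
#'   cationic, >= 3 tryptophans).
#' @slot nFamilies Number of planted families.
#' @slot familyDistances Per-family substitution fractions in [0, 1].
#' @slot membersPerFamily Members generated per family.
#' @slot withinFamilyDistance Substitution fraction of each member from its
#'   family center (pairwise within-family distance is about twice this).
#' @slot nDecoys Number of decoy proteins.
#' @slot decoyLengthRange Length range (min, max) of decoys; defaults straddle
#'   100 so the length filter is exercised.
#' @slot rngSeed Integer seed; a fixed seed yields byte-identical outputs.
#' @slot operonLayouts Layout tags from single, multi_2..multi_8, contig_edge,
#'   opposite_strand.
#' @export
setClass("SimConfig",
  representation(seedPeptide = "AAStringSet", nFamilies = "integer",
                 familyDistances = "numeric", membersPerFamily = "integer",
                 withinFamilyDistance = "numeric",
                 nDecoys = "integer", decoyLengthRange = "integer",
                 rngSeed = "integer", operonLayouts = "character"))

setValidity("SimConfig", function(object) {
  if (length(object@seedPeptide) != 1L) return("seedPeptide must be one sequence")
  if (any(object@familyDistances < 0 | object@familyDistances > 1))
    return("familyDistances must lie in [0, 1]")
  if (length(object@familyDistances) != object@nFamilies)
    return("need one distance per family")
  if (object@withinFamilyDistance < 0 || object@withinFamilyDistance > 1)
    return("withinFamilyDistance must lie in [0, 1]")
  if (object@nFamilies < 0L || object@membersPerFamily < 0L ||
      object@nDecoys < 0L)
    return("counts must be >= 0")
  if (length(object@decoyLengthRange) != 2L ||
      object@decoyLengthRange[1L] > object@decoyLengthRange[2L])
    return("decoyLengthRange must be (min, max) with min <= max")
  bad <- !grepl("^(single|multi_[2-8]|contig_edge|opposite_strand)$",
                object@operonLayouts)
  if (any(bad))
    return(paste("unknown operon layout:", object@operonLayouts[bad][1L]))
  TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: ", object@nFamilies, " families x ",
      object@membersPerFamily, " members + ", object@nDecoys,
      " decoys (", object@decoyLengthRange[1L], "-",
      object@decoyLengthRange[2L], " aa), seed ", object@rngSeed, "\n",
      sep = "")
})
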