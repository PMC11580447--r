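#' Default role keyword sets
#'
#' Case-insensitive substrings matched against CDS product annotations, in
#' fixed precedence order core > transport > membrane > regulator > repair >
#' hypothetical > other. The sets are data, overridable in
#' [classifyGeneRole()] and [extractBgc()].
#'
#' @return Named list of character vectors, in precedence order.
#' @export
roleKeywords <- function() {
  list(
    core = c("bacteriocin", "core peptide"),
    transport = c("ABC transporter", "ATP-binding", "efflux", "permease",
                  "AcrA", "membrane fusion protein"),
    membrane = c("PH domain", "bPH_2", "Yip1"),
    regulator = c("transcriptional regulator", "response regulator",
                  "helix-turn-helix", "LacI"),
    repair = c("excinuclease", "nucleotide excision repair"),
    hypothetical = "hypothetical")
}

#' Classify a gene product into a functional role
#'
#' First matching role by precedence; products matching nothing (including
#' the empty string) are \code{"other"}.
#'
#' @param product Product annotation text (vectorized).
#' @param keywords Keyword sets as from [roleKeywords()].
#' @return Character vector of roles.
#' @export
#' @examples
#' classifyGeneRole("PH domain-containing protein")
classifyGeneRole <- function(product, keywords = roleKeywords()) {
  vapply(product, function(p) {
    for (role in names(keywords)) {
      for (kw in keywords[[role]]) {
        if (grepl(kw, p, ignore.case = TRUE, fixed = FALSE)) return(role)
      }
    }
    "other"
  }, character(1L), USE.NAMES = FALSE)
}

#' Extract the BGC neighborhood around core-peptide genes
#'
#' Takes all CDS overlapping a window of \code{windowBp} on each side of the
#' span of the core genes (core genes within one window are merged into a
#' single BGC). Flags: \code{contig_edge} when the window is truncated by
#' the contig bounds; \code{opposite_strand_machinery} when any transport or
#' regulator feature lies on a different strand from the core;
#' \code{functional_operon} when transport machinery co-occurs with a
#' membrane or regulator gene.
#'
#' @param features GRanges of CDS for one contig (mcols gene_id, product).
#' @param coreIds gene_ids of the core-peptide genes (must be present).
#' @param contigLength Length of the contig in bp.
#' @param windowBp Window on each side of the core span (default 5000).
#' @param keywords Role keyword sets.
#' @return A [Bgc-class].
#' @export
extractBgc <- function(features, coreIds, contigLength, windowBp = 5000L,
                       keywords = roleKeywords()) {
  gid <- mcols(features)$gene_id
  missing <- setdiff(coreIds, gid)
  if (length(missing))
    stop("core gene id absent from features: ", missing[1L])
  coreFeat <- features[gid %in% coreIds]
  contig <- as.character(seqnames(features))[1L]
  spanStart <- min(start(coreFeat)); spanEnd <- max(end(coreFeat))
  rawStart <- spanStart - windowBp; rawEnd <- spanEnd + windowBp
  winStart <- max(1L, rawStart); winEnd <- min(as.integer(contigLength), rawEnd)
  contigEdge <- rawStart < 1L || rawEnd > contigLength

  inWin <- start(features) <= winEnd & end(features) >= winStart
  win <- features[inWin]
  role <- classifyGeneRole(mcols(win)$product, keywords)
  mcols(win)$role <- role
  coreStrand <- unique(as.character(strand(win))[role == "core"])
  machinery <- role %in% c("transport", "regulator")
  oppStrand <- any(machinery &
                     !as.character(strand(win)) %in% coreStrand)
  nCore <- sum(role == "core")
  flags <- c(has_transport = any(role == "transport"),
             has_membrane = any(role == "membrane"),
             has_regulator = any(role == "regulator"),
             contig_edge = contigEdge,
             opposite_strand_machinery = oppStrand)
  flags["functional_operon"] <-
    unname(flags["has_transport"] &&
             (flags["has_membrane"] || flags["has_regulator"]))
  new("Bgc", contig = contig,
      coreGeneIds = mcols(win)$gene_id[role == "core"],
      features = win, nCore = as.integer(nCore), flags = flags,
      category = if (nCore >= 2L) "multi" else "single",
      window = c(winStart, winEnd))
}

#' Tabulate BGCs by taxonomy and architecture
#'
#' @param bgcs List of [Bgc-class] objects.
#' @param taxonomy Optional data.frame (id, phylum, genus, species) keyed by
#'   contig id.
#' @return List of data.frames: \code{totals} (one row: n_bgcs,
#'   n_core_peptides, single, multi, plus flag frequencies) and
#'   \code{by_phylum} (per-phylum counts, ordered count desc then name asc;
#'   empty but well-formed when no taxonomy or no BGCs).
#' @export
tabulateBgcs <- function(bgcs, taxonomy = NULL) {
  emptyPhy <- data.frame(phylum = character(0), n_bgcs = integer(0),
                         n_core_peptides = integer(0))
  if (!length(bgcs)) {
    return(list(totals = data.frame(n_bgcs = 0L, n_core_peptides = 0L,
                                    single = 0L, multi = 0L,
                                    has_transport = 0L, has_membrane = 0L,
                                    has_regulator = 0L, contig_edge = 0L,
                                    opposite_strand_machinery = 0L,
                                    functional_operon = 0L),
                by_phylum = emptyPhy))
  }
  nCore <- vapply(bgcs, function(b) b@nCore, integer(1L))
  cat_ <- vapply(bgcs, function(b) b@category, character(1L))
  flags <- t(vapply(bgcs, function(b) b@flags, logical(6L)))
  totals <- data.frame(n_bgcs = length(bgcs), n_core_peptides = sum(nCore),
                       single = sum(cat_ == "single"),
                       multi = sum(cat_ == "multi"))
  totals <- cbind(totals, as.data.frame(t(colSums(flags))))
  byPhy <- emptyPhy
  if (!is.null(taxonomy)) {
    contigs <- vapply(bgcs, function(b) b@contig, character(1L))
    phy <- taxonomy$phylum[match(contigs, taxonomy$id)]
    phy[is.na(phy)] <- ""
    agg <- stats::aggregate(list(n_bgcs = rep(1L, length(phy)),
                                 n_core_peptides = nCore),
                            by = list(phylum = phy), FUN = sum)
    byPhy <- agg[order(-agg$n_bgcs, agg$phylum), , drop = FALSE]
    rownames(byPhy) <- NULL
  }
  list(totals = totals, by_phylum = byPhy)
}
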