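#' Run the full discovery pipeline on a synthetic study
#'
#' Orchestrates simulate, mine, properties and phylum contrast, identity
#' network, greedy clustering, tree and BGC-context stages from one
#' configuration with a single seed, the in-package equivalent of the
#' database-mining analysis workflow. With identical configuration and seed
#' the report is identical.
#'
#' @param simCfg A [SimConfig-class] describing the synthetic study.
#' @param eThreshold E-value gate for [iterativeSearch()] (default 1e-5).
#' @param maxLen Strict length filter (default 100).
#' @param nIterations Search rounds (default 2).
#' @param calibrationN Null sequences per calibration (default 1000).
#' @param ssnEdge SSN edge threshold in percent identity (default 64.29).
#' @param clusterId Greedy-cluster identity threshold (default 0.90).
#' @param windowBp BGC window (default 5000).
#' @param seedMsaRows,seedMsaDistance Shape of the generated seed alignment
#'   (default 6 rows at substitution distance 0.05).
#' @param outgroupId Optional outgroup tip for rooting the peptide tree.
#' @param outdir Optional directory; when given, every intermediate is
#'   serialized there (FASTA/TSV/GFF3/Newick).
#' @return A run-report list: \code{config}, \code{counts}, \code{truth},
#'   \code{hits}, \code{properties}, \code{contrast}, \code{identity},
#'   \code{ssn}, \code{clusters}, \code{tree} (Newick text or NA),
#'   \code{bgcs}, \code{bgcSummary}.
#' @export
runPipeline <- function(simCfg = simConfig(), eThreshold = 1e-5,
                        maxLen = 100L, nIterations = 2L,
                        calibrationN = 1000L, ssnEdge = 64.29,
                        clusterId = 0.90, windowBp = 5000L,
                        seedMsaRows = 6L, seedMsaDistance = 0.05,
                        outgroupId = NULL, outdir = NULL) {
  gen <- generateProteinDb(simCfg)     # seeds the RNG from simCfg@rngSeed
  seedMsa <- makeSeedAlignment(simCfg@seedPeptide, seedMsaRows,
                               seedMsaDistance)
  hits <- iterativeSearch(seedMsa, gen$db, eThreshold = eThreshold,
                          maxLen = maxLen, nIterations = nIterations,
                          calibrationN = calibrationN)
  phylum <- stats::setNames(gen$truth$phylum, gen$truth$id)

  hitSeqs <- gen$db[hits$sequence_id]
  props <- if (length(hitSeqs)) peptideProperties(hitSeqs) else
    data.frame(id = character(0), length = integer(0), gravy = numeric(0),
               mw = numeric(0), charge = numeric(0), pI = numeric(0))
  contrast <- NULL
  if (nrow(props) && length(unique(phylum[props$id])) >= 2L)
    contrast <- propertyContrast(props, phylum)

  im <- NULL; ssn <- NULL; cs <- NULL; nwk <- NA_character_
  if (length(hitSeqs) >= 1L) {
    im <- identityMatrix(hitSeqs)
    ssn <- buildSsn(im, ssnEdge, phylum)
    cs <- greedyCluster(hitSeqs, clusterId)
    reps <- clusterRepresentatives(cs)
    if (length(reps) >= 3L) {
      tree <- neighborJoining(distancesFromIdentity(im[reps, reps]))
      if (!is.null(outgroupId) && outgroupId %in% tree$tip.label)
        tree <- rootAtOutgroup(tree, outgroupId)
      nwk <- write.tree(tree)
    }
  }

  bgcs <- list()
  for (lay in simCfg@operonLayouts) {
    b <- generateSyntheticBgc(lay, simCfg@seedPeptide)
    bgcs[[lay]] <- extractBgc(b$features, b$coreIds, b$contigLength,
                              windowBp)
  }
  bgcSummary <- tabulateBgcs(bgcs)

  counts <- c(database = length(gen$db),
              planted = sum(gen$truth$kind == "planted"),
              decoys = sum(gen$truth$kind == "decoy"),
              hits = nrow(hits),
              clusters = if (is.null(cs)) 0L else
                length(clusterRepresentatives(cs)),
              ssn_components = if (is.null(ssn)) 0L else
                ssnSummary(ssn)$nComponents,
              bgcs = length(bgcs))

  report <- list(config = list(rngSeed = simCfg@rngSeed,
                               eThreshold = eThreshold, maxLen = maxLen,
                               ssnEdge = ssnEdge, clusterId = clusterId,
                               windowBp = windowBp),
                 counts = counts, truth = gen$truth, hits = hits,
                 properties = props, contrast = contrast, identity = im,
                 ssn = ssn, clusters = cs, tree = nwk, bgcs = bgcs,
                 bgcSummary = bgcSummary)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(gen$db, file.path(outdir, "database.faa"))
    writeFasta(seedMsa, file.path(outdir, "seed_msa.faa"))
    wt <- function(x, f) utils::write.table(
      x, file.path(outdir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(gen$truth, "truth.tsv")
    wt(hits, "hits.tsv")
    wt(props, "properties.tsv")
    if (!is.null(contrast)) wt(contrast, "contrast.tsv")
    if (!is.null(ssn)) writeSsn(ssn, file.path(outdir, "ssn_edges.tsv"),
                                file.path(outdir, "ssn_nodes.tsv"))
    if (!is.null(cs)) wt(cs@clusters, "clusters.tsv")
    if (!is.na(nwk)) writeLines(nwk, file.path(outdir, "peptide_tree.nwk"))
    wt(bgcSummary$totals, "bgc_totals.tsv")
  }
  report
}
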