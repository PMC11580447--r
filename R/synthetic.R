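#' Default seed core peptide
#'
#' A 52-residue synthetic cationic, tryptophan-rich peptide used as the
#' default family seed. It reproduces the *statistical* features of aureocin
#' A53-like core peptides — length ~50, net positive charge from K/R
#' enrichment, at least three tryptophans with W fixed at positions 21 and
#' 32 — without copying any real peptide sequence.
#'
#' @return AAStringSet of length 1, id \code{"seed_core"}.
#' @export
#' @examples
#' defaultSeedPeptide()
defaultSeedPeptide <- function() {
  s <- paste0("MGKIFGKAVQ", "RALDSKSGAK", "W", "KAGQKVVEAF", "W",
              "MNKGAKLAGR", "TVVKGLQHLW")
  stopifnot(nchar(s) == 52L,
            substr(s, 21L, 21L) == "W", substr(s, 32L, 32L) == "W")
  out <- AAStringSet(c(seed_core = s))
  mcols(out)$description <- "synthetic aureocin A53-like seed"
  out
}

# substitution distribution: background enriched in K/R (cationic bias)
cationicBackground <- function() {
  f <- backgroundFrequencies()
  f[c("K", "R")] <- f[c("K", "R")] * 3
  f / sum(f)
}

#' Mutate a peptide to a controlled substitution distance
#'
#' Substitutes exactly \code{round(fraction * length)} positions, chosen
#' without replacement, drawing replacement residues (always different from
#' the original) from a K/R-enriched background so the cationic character of
#' the family is preserved. At most one tryptophan is substituted per call
#' unless the requested distance forces more (e.g. \code{fraction = 1}).
#'
#' @param seed Seed sequence (AAStringSet of 1 or character).
#' @param fraction Substitution fraction in [0, 1].
#' @return Character scalar: the mutated sequence. The realized identity to
#'   the seed is \code{1 - round(fraction * length) / length}.
#' @export
mutatePeptide <- function(seed, fraction) {
  if (fraction < 0 || fraction > 1)
    stop("substitution fraction must lie in [0, 1]")
  s <- asSequenceString(seed)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  len <- length(chars)
  nSub <- round(fraction * len)
  if (nSub == 0L) return(s)
  wPos <- which(chars == "W")
  oPos <- which(chars != "W")
  pos <- sample.int(len, nSub)
  wSel <- intersect(pos, wPos)
  if (length(wSel) > 1L) {
    # keep one tryptophan substitution at most; move the surplus to unused
    # non-W positions (unless the distance forces more W losses)
    drop <- wSel[-1L]
    free <- setdiff(oPos, pos)
    nMove <- min(length(drop), length(free))
    if (nMove > 0L)
      pos <- c(setdiff(pos, drop[seq_len(nMove)]),
               free[sample.int(length(free), nMove)])
  }
  bg <- cationicBackground()
  aa <- aminoAcids()
  for (p in pos) {
    prob <- bg
    prob[chars[p]] <- 0
    chars[p] <- sample(aa, 1L, prob = prob)
  }
  paste(chars, collapse = "")
}

#' Synthetic-data configuration constructor
#'
#' @param seedPeptide Family seed; default [defaultSeedPeptide()].
#' @param nFamilies Number of planted families (default 2).
#' @param familyDistances Substitution fraction per family (default
#'   \code{c(0.1, 0.3)}).
#' @param membersPerFamily Members per family (default 10).
#' @param withinFamilyDistance Substitution fraction of members from their
#'   family center (default 0.05).
#' @param nDecoys Decoy proteins (default 200).
#' @param decoyLengthRange Decoy length range; the default \code{c(40, 130)}
#'   straddles 100 so the length filter is exercised.
#' @param rngSeed Integer seed for full determinism.
#' @param operonLayouts Operon layout tags for [generateSyntheticBgc()].
#' @return A validated [SimConfig-class].
#' @export
simConfig <- function(seedPeptide = defaultSeedPeptide(), nFamilies = 2L,
                      familyDistances = c(0.1, 0.3), membersPerFamily = 10L,
                      withinFamilyDistance = 0.05, nDecoys = 200L,
                      decoyLengthRange = c(40L, 130L), rngSeed = 1L,
                      operonLayouts = c("single", "multi_8", "contig_edge",
                                        "opposite_strand")) {
  new("SimConfig", seedPeptide = seedPeptide,
      nFamilies = as.integer(nFamilies),
      familyDistances = as.numeric(familyDistances),
      membersPerFamily = as.integer(membersPerFamily),
      withinFamilyDistance = as.numeric(withinFamilyDistance),
      nDecoys = as.integer(nDecoys),
      decoyLengthRange = as.integer(decoyLengthRange),
      rngSeed = as.integer(rngSeed),
      operonLayouts = operonLayouts)
}

#' Generate a synthetic protein database with a truth ledger
#'
#' Plants \code{nFamilies} peptide families and adds decoy proteins. Each
#' family has a center obtained by mutating the seed at the family's
#' substitution distance; members are mutated from that center at
#' \code{withinFamilyDistance}, so families are cohesive clusters placed at
#' controlled distances from the seed. Each decoy's residue composition is
#' drawn from a Dirichlet-smoothed global background (so decoys
#' carry no homologous signal and are suitable for E-value calibration).
#' When the decoy length range straddles 100, at least one decoy of >= 100
#' residues is guaranteed. Families alternate phylum labels (Actinomycetota,
#' Bacillota) so downstream group contrasts always have two non-empty
#' groups.
#'
#' @param config A [SimConfig-class].
#' @return List with \code{db} (AAStringSet) and \code{truth} (data.frame
#'   with columns id, kind, family, n_substituted, phylum, genus, species).
#'   The planted/decoy ids partition the database exactly.
#' @export
generateProteinDb <- function(config) {
  validObject(config)
  set.seed(config@rngSeed)
  seedSeq <- asSequenceString(config@seedPeptide)
  len <- nchar(seedSeq)
  aa <- aminoAcids()
  phyla <- c("Actinomycetota", "Bacillota")

  ids <- character(0); seqs <- character(0)
  truth <- list()
  for (f in seq_len(config@nFamilies)) {
    center <- mutatePeptide(seedSeq, config@familyDistances[f])
    for (m in seq_len(config@membersPerFamily)) {
      id <- sprintf("fam%d_m%d", f, m)
      sq <- mutatePeptide(center, config@withinFamilyDistance)
      ids <- c(ids, id); seqs <- c(seqs, sq)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, kind = "planted", family = f,
        n_substituted = sum(strsplit(sq, "")[[1L]] !=
                              strsplit(seedSeq, "")[[1L]]),
        phylum = phyla[(f - 1L) %% 2L + 1L],
        genus = sprintf("Genus%d", f), species = sprintf("species_f%d", f))
    }
  }

  rng <- config@decoyLengthRange
  if (config@nDecoys > 0L) {
    lens <- sample(seq(rng[1L], rng[2L]), config@nDecoys, replace = TRUE)
    if (rng[1L] < 100L && rng[2L] >= 100L && !any(lens >= 100L))
      lens[1L] <- 100L
    bg <- backgroundFrequencies()
    for (i in seq_len(config@nDecoys)) {
      comp <- stats::rgamma(20L, shape = bg * 50)
      comp <- comp / sum(comp)
      id <- sprintf("decoy_%04d", i)
      sq <- paste(sample(aa, lens[i], replace = TRUE, prob = comp),
                  collapse = "")
      ids <- c(ids, id); seqs <- c(seqs, sq)
      truth[[length(truth) + 1L]] <- data.frame(
        id = id, kind = "decoy", family = NA_integer_, n_substituted = NA_integer_,
        phylum = phyla[(i - 1L) %% 2L + 1L],
        genus = "DecoyGenus", species = sprintf("decoy_sp%d", (i - 1L) %% 5L + 1L))
    }
  }

  db <- AAStringSet(seqs)
  names(db) <- ids
  mcols(db)$description <- ""
  list(db = db, truth = do.call(rbind, truth))
}

#' Generate an ungapped seed alignment around the seed peptide
#'
#' Produces \code{n} low-distance variants of the seed (substitutions only,
#' so rows are already aligned) to stand in for the alignment of known core
#' peptides from which the first search model is built.
#'
#' @param seed Seed sequence.
#' @param n Number of rows (default 6).
#' @param distance Substitution fraction per row (default 0.05).
#' @return AAStringSet alignment of \code{n} rows.
#' @export
makeSeedAlignment <- function(seed = defaultSeedPeptide(), n = 6L,
                              distance = 0.05) {
  s <- asSequenceString(seed)
  rows <- vapply(seq_len(n), function(i) mutatePeptide(s, distance),
                 character(1L))
  out <- AAStringSet(rows)
  names(out) <- sprintf("seed_%02d", seq_len(n))
  out
}

layoutRoles <- function() {
  list(core = "aureocin A53 family leaderless bacteriocin core peptide",
       transport = "ABC transporter ATP-binding protein",
       membrane = "PH domain-containing protein",
       regulator = "transcriptional regulator",
       hypothetical = "hypothetical protein")
}

#' Generate a synthetic BGC feature table for an operon layout
#'
#' Emits CDS features for one contig following an operon archetype:
#' \describe{
#'   \item{single}{one core-peptide gene with transport, membrane and
#'     regulator genes on the same strand.}
#'   \item{multi_k (k = 2..8)}{k core genes within one operon window.}
#'   \item{contig_edge}{as single, but the contig ends less than 2 kb after
#'     the core gene.}
#'   \item{opposite_strand}{transporter and regulator on the minus strand
#'     with the core on plus.}
#' }
#'
#' @param layout Layout tag.
#' @param core Core peptide sequence (sets the core gene length, 3 nt per
#'   residue plus stop).
#' @param contig Contig id (default derived from the layout).
#' @return List with \code{features} (GRanges with mcols gene_id, product),
#'   \code{contigLength}, \code{coreIds}, \code{layout}.
#' @export
generateSyntheticBgc <- function(layout, core = defaultSeedPeptide(),
                                 contig = paste0("contig_", layout)) {
  mk <- regmatches(layout, regexec("^multi_([2-8])$", layout))[[1L]]
  nCore <- if (length(mk)) as.integer(mk[2L]) else 1L
  if (!length(mk) && !layout %in% c("single", "contig_edge", "opposite_strand"))
    stop("unknown operon layout: ", layout)
  roles <- layoutRoles()
  coreLen <- 3L * nchar(asSequenceString(core)) + 3L

  products <- character(0); strands <- character(0); lens <- integer(0)
  add <- function(p, s, l) {
    products <<- c(products, p); strands <<- c(strands, s)
    lens <<- c(lens, as.integer(l))
  }
  accStrand <- if (layout == "opposite_strand") "-" else "+"
  add(roles$hypothetical, "+", 300L)
  add(roles$transport, accStrand, 750L)
  add(roles$membrane, "+", 450L)
  for (i in seq_len(nCore)) add(roles$core, "+", coreLen)
  add(roles$regulator, accStrand, 600L)
  add(roles$hypothetical, "+", 300L)

  gap <- sample(60:180, length(lens), replace = TRUE)
  startAt <- 6000L
  starts <- integer(length(lens)); ends <- integer(length(lens))
  pos <- startAt
  for (i in seq_along(lens)) {
    starts[i] <- pos
    ends[i] <- pos + lens[i] - 1L
    pos <- ends[i] + gap[i]
  }
  contigLength <- if (layout == "contig_edge") {
    coreEnd <- ends[which(products == roles$core)[nCore]]
    coreEnd + sample(200:1500, 1L)
  } else ends[length(ends)] + 6000L
  keep <- ends <= contigLength
  products <- products[keep]; strands <- strands[keep]
  starts <- starts[keep]; ends <- ends[keep]

  isCore <- products == roles$core
  ord <- seq_along(products)
  geneIds <- sprintf("%s_g%02d", contig, ord)
  gr <- GRanges(seqnames = contig,
                ranges = IRanges(start = starts, end = ends),
                strand = strands, gene_id = geneIds, product = products)
  list(features = gr, contigLength = as.integer(contigLength),
       coreIds = geneIds[isCore], layout = layout)
}

#' Write a full synthetic study to disk
#'
#' Runs [generateProteinDb()] and [generateSyntheticBgc()] for every
#' configured layout and writes FASTA, GFF3, taxonomy TSV and truth TSV into
#' \code{outdir}. With a fixed \code{rngSeed} the outputs are byte-identical
#' across runs.
#'
#' @param config A [SimConfig-class].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a named list of the written paths.
#' @export
simulateStudy <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gen <- generateProteinDb(config)
  p <- list(db = file.path(outdir, "database.faa"),
            truth = file.path(outdir, "truth.tsv"),
            taxonomy = file.path(outdir, "taxonomy.tsv"),
            features = file.path(outdir, "features.gff3"),
            contigs = file.path(outdir, "contigs.tsv"))
  writeFasta(gen$db, p$db)
  utils::write.table(gen$truth, p$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tax <- data.frame(id = gen$truth$id, phylum = gen$truth$phylum,
                    genus = gen$truth$genus, species = gen$truth$species)
  writeTaxonomy(tax, p$taxonomy)
  feats <- list(); contigs <- list()
  for (lay in config@operonLayouts) {
    b <- generateSyntheticBgc(lay, config@seedPeptide)
    feats[[lay]] <- b$features
    contigs[[lay]] <- data.frame(contig = paste0("contig_", lay),
                                 length = b$contigLength, layout = lay)
  }
  # contigs are distinct by construction, so merging their seqlevels is the
  # intended behaviour, not a mixup worth warning about
  allFeats <- suppressWarnings(do.call(c, unname(feats)))
  writeFeatures(allFeats, p$features)
  utils::write.table(do.call(rbind, contigs), p$contigs, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(p)
}
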