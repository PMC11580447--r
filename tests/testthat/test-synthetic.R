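test_that("mutatePeptide realizes the exact substitution count", {
  seed <- asSeq <- as.character(defaultSeedPeptide()[[1L]])
  set.seed(11)
  # fraction 0 leaves the sequence untouched
  expect_identical(mutatePeptide(seed, 0), seed)

  # fraction 1 on a length-10 seed substitutes all 10 positions
  s10 <- "MKWAGKLKRV"
  m10 <- mutatePeptide(s10, 1)
  hamming <- function(a, b) sum(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
  expect_identical(hamming(s10, m10), 10L)

  # fraction 0.2 on the 52-aa seed: round(0.2 * 52) = 10 differences,
  # recounted by independent character comparison, over repeated draws
  for (i in 1:20) {
    m <- mutatePeptide(seed, 0.2)
    expect_identical(hamming(seed, m), 10L)
  }
  expect_error(mutatePeptide(seed, 1.2), "fraction")
})

test_that("mutatePeptide loses at most one tryptophan unless forced", {
  seed <- as.character(defaultSeedPeptide()[[1L]])
  nW <- function(s) sum(strsplit(s, "")[[1L]] == "W")
  set.seed(7)
  for (i in 1:40) {
    m <- mutatePeptide(seed, 0.3)
    expect_gte(nW(m), nW(seed) - 1L)
  }
})

test_that("generateProteinDb plants families, decoys and a complete ledger", {
  cfg <- simConfig(nFamilies = 2L, familyDistances = c(0.1, 0.6),
                   membersPerFamily = 3L, nDecoys = 5L, rngSeed = 5L)
  gen <- generateProteinDb(cfg)
  expect_length(gen$db, 11L)  # 6 planted + 5 decoys
  expect_identical(sum(gen$truth$kind == "planted"), 6L)
  # ledger partitions the database exactly
  expect_setequal(gen$truth$id, names(gen$db))
  expect_identical(anyDuplicated(gen$truth$id), 0L)
  expect_length(intersect(gen$truth$id[gen$truth$kind == "planted"],
                          gen$truth$id[gen$truth$kind == "decoy"]), 0L)
  # family phyla alternate so the group contrast has two non-empty groups
  expect_setequal(unique(gen$truth$phylum[gen$truth$kind == "planted"]),
                  c("Actinomycetota", "Bacillota"))

  # identity ordering: distance-0.1 members are closer to the seed than
  # distance-0.6 members, verified by pairwise Hamming identity
  seed <- as.character(cfg@seedPeptide[[1L]])
  idTo <- function(s) mean(strsplit(s, "")[[1L]] == strsplit(seed, "")[[1L]])
  f1 <- vapply(as.character(gen$db[gen$truth$id[gen$truth$family %in% 1L]]),
               idTo, numeric(1L))
  f2 <- vapply(as.character(gen$db[gen$truth$id[gen$truth$family %in% 2L]]),
               idTo, numeric(1L))
  expect_true(min(f1) > max(f2))
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- simConfig(nDecoys = 20L, membersPerFamily = 4L, rngSeed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulateStudy(cfg, d1)
  simulateStudy(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("decoy lengths straddling 100 include proteins at or over 100", {
  cfg <- simConfig(nDecoys = 30L, decoyLengthRange = c(40L, 130L),
                   rngSeed = 3L)
  gen <- generateProteinDb(cfg)
  decoyW <- Biostrings::width(gen$db[gen$truth$id[gen$truth$kind == "decoy"]])
  expect_true(any(decoyW >= 100L))
  expect_true(any(decoyW < 100L))
})

test_that("synthetic BGC layouts realize their architectures", {
  set.seed(2)
  single <- generateSyntheticBgc("single")
  core <- grepl("core peptide", S4Vectors::mcols(single$features)$product)
  expect_identical(sum(core), 1L)

  multi <- generateSyntheticBgc("multi_8")
  coreM <- grepl("core peptide", S4Vectors::mcols(multi$features)$product)
  expect_identical(sum(coreM), 8L)
  # all eight core genes on one contig within a single operon window
  coreFeat <- multi$features[coreM]
  expect_lt(max(GenomicRanges::end(coreFeat)) -
              min(GenomicRanges::start(coreFeat)), 5000L)

  opp <- generateSyntheticBgc("opposite_strand")
  prods <- S4Vectors::mcols(opp$features)$product
  coreStrand <- as.character(GenomicRanges::strand(
    opp$features[grepl("core peptide", prods)]))
  trStrand <- as.character(GenomicRanges::strand(
    opp$features[grepl("ABC transporter", prods)]))
  expect_false(any(trStrand == coreStrand))

  edge <- generateSyntheticBgc("contig_edge")
  coreEnd <- max(GenomicRanges::end(
    edge$features[grepl("core peptide",
                        S4Vectors::mcols(edge$features)$product)]))
  expect_lt(edge$contigLength - coreEnd, 2000L)

  expect_error(generateSyntheticBgc("circular"), "unknown")
})
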