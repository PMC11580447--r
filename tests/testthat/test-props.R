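test_that("GRAVY matches the Kyte-Doolittle table", {
  expect_identical(gravy("I"), 4.5)
  expect_identical(gravy("IR"), 0)      # (4.5 - 4.5) / 2
  set.seed(4)
  s <- randomPeptide(30)
  rev_ <- paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  expect_equal(gravy(s), gravy(rev_))
  expect_error(gravy("MKX"), "canonical")
  expect_error(gravy(""), "non-empty")
})

test_that("molecular weight is additive residue masses plus one water", {
  expect_equal(molecularWeight("G"), 57.0519 + 18.0153)
  s <- "MKWAG"; t_ <- "LLRV"
  expect_equal(molecularWeight(paste0(s, t_)),
               molecularWeight(s) + molecularWeight(t_) - 18.0153)
  # a 52-aa cationic W-rich peptide sits in the 5-7 kDa band
  mw <- molecularWeight(as.character(defaultSeedPeptide()[[1L]]))
  expect_gt(mw, 5000); expect_lt(mw, 7000)
})

test_that("net charge follows Henderson-Hasselbalch with EMBOSS pKs", {
  # poly-G at pH 7: termini only, N-term pK 8.6 and C-term pK 3.6
  expected <- 1 / (1 + 10^(7 - 8.6)) - 1 / (1 + 10^(3.6 - 7))
  expect_equal(netCharge("GGGGG", 7), expected)
  expect_lt(abs(netCharge("GGGGG", 7)), 0.05)

  # lysine at very low pH approaches +2 (N-terminus + side chain)
  expect_equal(netCharge("K", 0), 2, tolerance = 2e-3)

  # strictly decreasing in pH for random peptides
  set.seed(8)
  for (i in 1:5) {
    s <- randomPeptide(25)
    ch <- vapply(seq(0, 14, by = 0.5), function(p) netCharge(s, p),
                 numeric(1L))
    expect_true(all(diff(ch) < 0), info = s)
  }
  expect_error(netCharge("K", 15), "pH")
})

test_that("the isoelectric point is the root of the charge curve", {
  set.seed(12)
  for (i in 1:20) {
    s <- randomPeptide(sample(10:60, 1L))
    pI <- isoelectricPoint(s)
    if (is.null(attr(pI, "boundary")))
      expect_lte(abs(netCharge(s, as.numeric(pI))), 1e-3)
  }
  # basic-residue-rich peptides have higher pI than acidic ones
  expect_gt(isoelectricPoint(strrep("KR", 5)),
            isoelectricPoint(strrep("DE", 5)))
  expect_gt(isoelectricPoint(strrep("K", 10)), 10)
})

test_that("dose conversion reproduces the assay arithmetic", {
  expect_identical(doseToMolar(100, 6300), 15.9)
  expect_identical(doseToMolar(5.7, 5700), 1)     # dose = MW/1000 => 1 uM
  expect_identical(doseToMolar(200, 5000), 2 * doseToMolar(100, 5000))
  expect_error(doseToMolar(-1, 6300), "positive")
})

test_that("Kruskal-Wallis H matches hand computation and the permutation law", {
  kt <- kruskalWallis(1:6, rep(c("a", "b"), each = 3))
  expect_equal(kt$H, 3.857143, tolerance = 1e-6)
  expect_identical(kt$df, 1L)

  # identical values: H = 0, p = 1
  flat <- kruskalWallis(rep(2, 6), rep(c("a", "b"), each = 3))
  expect_identical(flat$H, 0)
  expect_identical(flat$p, 1)

  # chi-square p tracks the exact permutation distribution at n = (4, 4);
  # the chi-square approximation error at this sample size can reach ~0.13
  set.seed(21)
  for (i in 1:5) {
    x <- round(stats::rnorm(4, 0, 2), 2); y <- round(stats::rnorm(4, 1.5, 2), 2)
    pPkg <- kruskalWallis(c(x, y), rep(c("g1", "g2"), each = 4))$p
    pPerm <- oracleKwPermutation(x, y)
    expect_lt(abs(pPkg - pPerm), 0.15, label = paste("case", i))
  }

  # H is invariant to monotone transforms of the data
  set.seed(34)
  v <- stats::rnorm(12); g <- rep(c("a", "b", "c"), each = 4)
  expect_equal(kruskalWallis(v, g)$H, kruskalWallis(exp(v), g)$H)

  expect_error(kruskalWallis(1:3, rep("a", 3)), "2 groups")
})

test_that("property tables and the phylum contrast are well-formed", {
  set.seed(44)
  seqs <- Biostrings::AAStringSet(vapply(1:8, function(i)
    mutatePeptide(as.character(defaultSeedPeptide()[[1L]]), 0.2), ""))
  names(seqs) <- paste0("p", 1:8)
  props <- peptideProperties(seqs)
  expect_identical(nrow(props), 8L)
  expect_true(all(props$mw > 0))
  expect_true(all(props$pI > 0 & props$pI < 14))
  expect_true(all(abs(props$gravy) <= 4.5))

  phy <- stats::setNames(rep(c("Actinomycetota", "Bacillota"), 4L),
                         names(seqs))
  ct <- propertyContrast(props, phy)
  expect_identical(ct$property, c("length", "gravy", "mw", "charge", "pI"))
  expect_true(all(ct$p >= 0 & ct$p <= 1))
})
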