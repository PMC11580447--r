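test_that("identity-to-distance conversion", {
  m <- matrix(c(100, 26.9, 26.9, 100), 2, 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  d <- distancesFromIdentity(m)
  expect_identical(diag(d), c(a = 0, b = 0))
  expect_equal(d["a", "b"], 0.731)
  expect_identical(d, t(d))
})

test_that("neighbor joining recovers additive matrices exactly", {
  set.seed(52)
  for (n in 4:8) {
    ref <- randomAdditiveMatrix(n)
    tr <- neighborJoining(ref$dm)
    expect_identical(sort(tr$tip.label), sort(rownames(ref$dm)))
    # topology: Robinson-Foulds distance to the generating tree is 0
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr),
                                               ape::unroot(ref$tree))), 0)
    # branch lengths: leaf-to-leaf path lengths reproduce the input matrix
    co <- ape::cophenetic.phylo(tr)[rownames(ref$dm), colnames(ref$dm)]
    expect_equal(co, ref$dm, tolerance = 1e-9)
  }
})

test_that("the two closest taxa join first in an ultrametric case", {
  dm <- matrix(c(0, 1, 4,
                 1, 0, 4,
                 4, 4, 0), 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighborJoining(dm)
  co <- ape::cophenetic.phylo(tr)
  expect_equal(co["a", "b"], 1)
  expect_error(neighborJoining(dm[1:2, 1:2]), "at least 3")
})

test_that("taxon input order does not change the inferred tree", {
  set.seed(58)
  ref <- randomAdditiveMatrix(6L)
  tr1 <- neighborJoining(ref$dm)
  perm <- sample(6L)
  tr2 <- neighborJoining(ref$dm[perm, perm])
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr1),
                                             ape::unroot(tr2))), 0)
  ids <- rownames(ref$dm)
  expect_equal(ape::cophenetic.phylo(tr1)[ids, ids],
               ape::cophenetic.phylo(tr2)[ids, ids], tolerance = 1e-9)
})

test_that("package NJ agrees with the ape reference implementation", {
  set.seed(64)
  base <- randomPeptide(40)
  seqs <- Biostrings::AAStringSet(vapply(1:6, function(i)
    mutatePeptide(base, runif(1, 0.1, 0.6)), ""))
  names(seqs) <- paste0("p", 1:6)
  dm <- distancesFromIdentity(identityMatrix(seqs))
  mine <- neighborJoining(dm)
  ref <- ape::nj(stats::as.dist(dm))
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(mine),
                                             ape::unroot(ref))), 0)
})

test_that("outgroup rooting splits the pendant branch at its midpoint", {
  dm <- matrix(c(0, 2, 4, 4,
                 2, 0, 4, 4,
                 4, 4, 0, 2,
                 4, 4, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighborJoining(dm)
  rt <- rootAtOutgroup(tr, "a")
  expect_true(ape::is.rooted(rt))
  # the outgroup's sister clade contains all remaining taxa
  rootNode <- length(rt$tip.label) + 1L
  kids <- rt$edge[rt$edge[, 1L] == rootNode, 2L]
  ogTip <- which(rt$tip.label == "a")
  expect_true(ogTip %in% kids)
  # path lengths between the ingroup taxa are untouched
  expect_equal(ape::cophenetic.phylo(rt)[letters[2:4], letters[2:4]],
               ape::cophenetic.phylo(tr)[letters[2:4], letters[2:4]],
               tolerance = 1e-12)
  # unrooted topology unchanged by rooting
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(rt),
                                             ape::unroot(tr))), 0)
  # pendant branch split in half: both root child edges carry half each
  og <- rt$edge[, 2L] == ogTip & rt$edge[, 1L] == rootNode
  expect_equal(rt$edge.length[og],
               tr$edge.length[tr$edge[, 2L] == which(tr$tip.label == "a")] / 2)
  expect_error(rootAtOutgroup(tr, "zz"), "zz")
})

test_that("Newick serialization round-trips", {
  set.seed(71)
  ref <- randomAdditiveMatrix(5L)
  tr <- neighborJoining(ref$dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  writeNewick(tr, f)
  back <- readNewick(f)
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
  ids <- tr$tip.label
  expect_equal(ape::cophenetic.phylo(back)[ids, ids],
               ape::cophenetic.phylo(tr)[ids, ids], tolerance = 1e-8)
})
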