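#' @importFrom ape read.tree write.tree root
NULL

#' Distance matrix from percent identities
#'
#' \code{d = 1 - pid / 100}: identical peptides are at distance 0, fully
#' dissimilar ones at 1.
#'
#' @param m Identity matrix from [identityMatrix()].
#' @return Symmetric distance matrix with zero diagonal.
#' @export
distancesFromIdentity <- function(m) {
  d <- 1 - m / 100
  diag(d) <- 0
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix. At each step the pair
#' minimizing the Q criterion is joined (ties broken by the smallest (i, j)
#' index pair); negative branch lengths are clamped to zero with the deficit
#' moved to the sister branch. The result is an unrooted tree stored with an
#' arbitrary trifurcating root; it recovers any additive matrix exactly.
#'
#' @param dm Symmetric distance matrix with ids as dimnames (>= 3 taxa).
#' @return An ape \code{phylo} tree.
#' @export
neighborJoining <- function(dm) {
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("t", seq_len(n))
  D <- unname(as.matrix(dm))
  frag <- ids                      # newick fragment per active node

  fmtLen <- function(x) formatC(x, format = "g", digits = 15)
  while (length(frag) > 3L) {
    k <- nrow(D)
    r <- rowSums(D)
    Q <- (k - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      if (Q[i, j] < bq - 1e-12) { bq <- Q[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newFrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmtLen(bi),
                       frag[j], fmtLen(bj))
    newD <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(k), c(i, j))
    D2 <- matrix(0, k - 1L, k - 1L)
    D2[seq_along(keep), seq_along(keep)] <- D[keep, keep]
    D2[k - 1L, seq_along(keep)] <- D2[seq_along(keep), k - 1L] <- newD[keep]
    D <- D2
    frag <- c(frag[keep], newFrag)
  }
  da <- D[1L, 2L]; db <- D[1L, 3L]; dc <- D[2L, 3L]
  b1 <- max(0, (da + db - dc) / 2)
  b2 <- max(0, (da + dc - db) / 2)
  b3 <- max(0, (db + dc - da) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", frag[1L], fmtLen(b1),
                 frag[2L], fmtLen(b2), frag[3L], fmtLen(b3))
  read.tree(text = nwk)
}

#' Root a tree at an outgroup
#'
#' Places the root at the midpoint of the outgroup's pendant branch; all
#' other relationships (and all path lengths between the remaining taxa) are
#' preserved.
#'
#' @param tree An ape \code{phylo}.
#' @param outgroupLabel Tip label of the outgroup; a missing label is a hard
#'   error naming it.
#' @return A rooted \code{phylo}.
#' @export
rootAtOutgroup <- function(tree, outgroupLabel) {
  if (!outgroupLabel %in% tree$tip.label)
    stop("outgroup label not among tree tips: ", outgroupLabel)
  rt <- root(tree, outgroup = outgroupLabel, resolve.root = TRUE)
  rootNode <- length(rt$tip.label) + 1L
  kids <- which(rt$edge[, 1L] == rootNode)
  tipIdx <- which(rt$tip.label == outgroupLabel)
  ogEdge <- kids[rt$edge[kids, 2L] == tipIdx]
  sisEdge <- setdiff(kids, ogEdge)
  stopifnot(length(ogEdge) == 1L, length(sisEdge) == 1L)
  half <- rt$edge.length[ogEdge] / 2
  rt$edge.length[ogEdge] <- rt$edge.length[ogEdge] - half
  rt$edge.length[sisEdge] <- rt$edge.length[sisEdge] + half
  rt
}

#' Newick serialization
#'
#' @param tree An ape \code{phylo}.
#' @param path File path.
#' @return \code{readNewick}: a \code{phylo}; \code{writeNewick}: the path,
#'   invisibly.
#' @export
writeNewick <- function(tree, path) {
  write.tree(tree, file = path)
  invisible(path)
}

#' @rdname writeNewick
#' @export
readNewick <- function(path) read.tree(path)
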