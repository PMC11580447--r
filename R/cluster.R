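#' @importFrom igraph graph_from_data_frame components V
NULL

#' All-vs-all percent-identity matrix
#'
#' Global percent identity ([percentIdentity()] of [globalAlign()]) for every
#' unordered pair; diagonal exactly 100.
#'
#' @param records AAStringSet (>= 1, named).
#' @param scheme A [ScoringScheme-class].
#' @return Symmetric numeric matrix with the sequence ids as dimnames.
#' @export
identityMatrix <- function(records, scheme = scoringScheme()) {
  n <- length(records)
  stopifnot(n >= 1L)
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  seqs <- as.character(records)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      p <- percentIdentity(globalAlign(seqs[i], seqs[j], scheme))
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}

#' Build a sequence similarity network
#'
#' Edges connect peptide pairs with percent identity strictly greater than
#' the threshold (so singletons are exactly the peptides with < threshold
#' identity to every other peptide). Connected components are the peptide
#' groups; component labels are ordered by size descending, then by smallest
#' member id.
#'
#' @param m Identity matrix from [identityMatrix()].
#' @param edgeThreshold Edge threshold in percent (default 64.29).
#' @param phylum Optional named vector mapping peptide id to phylum.
#' @return An [Ssn-class].
#' @export
buildSsn <- function(m, edgeThreshold = 64.29, phylum = NULL) {
  ids <- rownames(m)
  n <- length(ids)
  src <- character(0); tgt <- character(0); pid <- numeric(0)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (m[i, j] > edgeThreshold) {
        src <- c(src, ids[i]); tgt <- c(tgt, ids[j]); pid <- c(pid, m[i, j])
      }
    }
  }
  edges <- data.frame(source = src, target = tgt, pid = pid)
  g <- graph_from_data_frame(edges, directed = FALSE,
                             vertices = data.frame(name = ids))
  cmp <- components(g)
  degree <- igraph::degree(g)[ids]
  membership <- cmp$membership[ids]
  # stable component labels: size desc, then smallest member id
  sizes <- table(membership)
  firstId <- vapply(names(sizes), function(k)
    min(ids[membership == as.integer(k)]), character(1L))
  ord <- order(-as.integer(sizes), firstId)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  nodes <- data.frame(
    id = ids,
    phylum = if (is.null(phylum)) rep("", n) else unname(phylum[ids]),
    component = unname(relabel[as.character(membership)]),
    degree = as.integer(degree))
  new("Ssn", nodes = nodes, edges = edges,
      threshold = edgeThreshold)
}

#' Components and singletons of an SSN
#'
#' @param ssn An [Ssn-class].
#' @return List with \code{nComponents} (all components, singletons
#'   included), \code{nNonSingleton} (groups of >= 2), and \code{singletons}
#'   (ids).
#' @export
ssnSummary <- function(ssn) {
  sing <- ssn@nodes$id[ssn@nodes$degree == 0L]
  list(nComponents = length(unique(ssn@nodes$component)),
       nNonSingleton = length(unique(
         ssn@nodes$component[ssn@nodes$degree > 0L])),
       singletons = sing)
}

#' Greedy identity clustering (CD-HIT style)
#'
#' Sequences are sorted by length descending (ties broken by id); the longest
#' unassigned sequence founds a cluster and each subsequent sequence joins
#' the first existing representative it matches at or above the identity
#' threshold, else founds its own cluster. Exact global percent identities
#' are used (no word-filter heuristics).
#'
#' @param records Named AAStringSet.
#' @param threshold Identity threshold as a fraction (default 0.90).
#' @param scheme A [ScoringScheme-class].
#' @return A [ClusterSet-class].
#' @export
greedyCluster <- function(records, threshold = 0.90,
                          scheme = scoringScheme()) {
  ids <- names(records)
  ord <- order(-width(records), ids)
  seqs <- as.character(records)[ord]
  ids <- ids[ord]
  repIds <- character(0)
  assignment <- character(length(ids))
  for (i in seq_along(ids)) {
    placed <- FALSE
    for (r in repIds) {
      p <- percentIdentity(globalAlign(seqs[match(r, ids)], seqs[i], scheme))
      if (p >= 100 * threshold) {
        assignment[i] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      repIds <- c(repIds, ids[i])
      assignment[i] <- ids[i]
    }
  }
  new("ClusterSet",
      clusters = data.frame(representative = assignment, member = ids),
      threshold = threshold)
}

#' Cluster representatives
#'
#' @param cs A [ClusterSet-class].
#' @return Character vector of representative ids, in founding order.
#' @export
clusterRepresentatives <- function(cs) unique(cs@clusters$representative)

#' Export an SSN as edge-list and node-attribute tables
#'
#' @param ssn An [Ssn-class].
#' @param edgePath,nodePath Output TSV paths.
#' @return Invisibly, both paths.
#' @export
writeSsn <- function(ssn, edgePath, nodePath) {
  utils::write.table(ssn@edges, edgePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ssn@nodes, nodePath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(edgePath, nodePath))
}
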