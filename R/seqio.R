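#' @importClassesFrom Biostrings AAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

validateSequenceSet <- function(x, what = "sequence") {
  if (!length(x)) return(invisible(x))
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every ", what, " must have a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence id: ", ids[duplicated(ids)][1L])
  if (any(width(x) < 1L))
    stop("empty sequence for id: ", ids[width(x) < 1L][1L])
  ok <- paste0(aminoAcids(), collapse = "")
  for (i in seq_along(x)) {
    s <- as.character(x[[i]])
    bad <- regexpr(paste0("[^", ok, "X]"), s)
    if (bad > 0L)
      stop("invalid residue '", substr(s, bad, bad), "' at position ", bad,
           " in sequence ", ids[i])
  }
  invisible(x)
}

#' Read a validated protein FASTA file
#'
#' Strict FASTA reader for core peptides and database proteins. Sequences are
#' upper-cased, a single trailing stop character \code{*} is stripped, and the
#' file is rejected (never silently repaired) on duplicate ids, empty
#' sequences, or residues outside the 20 canonical amino acids plus X.
#'
#' @param path Path to a FASTA file.
#' @return An [Biostrings::AAStringSet] named by the id token (first
#'   whitespace-delimited word of the header), with the remainder of the
#'   header in \code{mcols(x)$description}.
#' @seealso [writeFasta()]
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readAAStringSet(path)
  headers <- names(raw)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(raw))
  seqs <- sub("\\*$", "", seqs)
  out <- AAStringSet(seqs)
  names(out) <- ids
  mcols(out)$description <- desc
  validateSequenceSet(out)
  out
}

#' Write sequences as 60-column wrapped FASTA
#'
#' @param x AAStringSet (optionally with \code{mcols(x)$description}) or a
#'   named character vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
writeFasta <- function(x, path) {
  if (is.character(x)) {
    x <- AAStringSet(x)
  }
  validateSequenceSet(x)
  desc <- mcols(x)$description
  nm <- names(x)
  if (!is.null(desc) && any(nzchar(desc)))
    nm <- ifelse(nzchar(desc), paste(nm, desc), nm)
  names(x) <- nm
  writeXStringSet(x, path, width = 60L)
  invisible(path)
}

#' Read CDS features from a GFF3-subset file
#'
#' Reads a 9-column GFF3 feature table, keeping only rows of type \code{CDS}.
#' Coordinates are 1-based inclusive as in GFF3; \code{ID=} and
#' \code{product=} are parsed from the attribute column (product defaults to
#' the empty string). Rows with \code{end < start} or a strand other than
#' \code{+}/\code{-} are hard errors.
#'
#' @param path Path to a GFF3-subset file; \code{##}-comment lines are
#'   tolerated.
#' @return A [GenomicRanges::GRanges] with mcols \code{gene_id} and
#'   \code{product}.
#' @export
readFeatures <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines)) return(emptyFeatures())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9L))
    stop("GFF3 row with ", nf[nf != 9L][1L], " columns (expected 9)")
  tab <- do.call(rbind, parts)
  keep <- tab[, 3L] == "CDS"
  tab <- tab[keep, , drop = FALSE]
  if (!nrow(tab)) return(emptyFeatures())
  start <- as.integer(tab[, 4L]); end <- as.integer(tab[, 5L])
  if (anyNA(start) || anyNA(end)) stop("non-numeric coordinates in GFF3")
  if (any(end < start))
    stop("feature with end < start on contig ", tab[end < start, 1L][1L])
  if (any(start < 1L)) stop("GFF3 coordinates are 1-based; start < 1 found")
  strand <- tab[, 7L]
  bad <- !strand %in% c("+", "-")
  if (any(bad)) stop("unknown strand symbol '", strand[bad][1L], "'")
  attr9 <- tab[, 9L]
  getAttr <- function(key) {
    vapply(regmatches(attr9, gregexpr(paste0("(^|;)", key, "=[^;]*"), attr9)),
           function(h) if (length(h) && nzchar(h[1L]))
             sub(paste0("^;?", key, "="), "", h[1L]) else "",
           character(1L))
  }
  GRanges(seqnames = tab[, 1L],
          ranges = IRanges(start = start, end = end),
          strand = strand,
          gene_id = getAttr("ID"),
          product = getAttr("product"))
}

emptyFeatures <- function() {
  GRanges(gene_id = character(0), product = character(0))
}

#' Write CDS features as GFF3
#'
#' Inverse of [readFeatures()]: serializes a GRanges of CDS features to a
#' 9-column GFF3-subset file with \code{ID=} and \code{product=} attributes.
#'
#' @param gr GRanges with mcols \code{gene_id} and \code{product}.
#' @param path Output path.
#' @param source Value for the source column (default \code{"aureomine"}).
#' @return Invisibly, the path.
#' @export
writeFeatures <- function(gr, path, source = "aureomine") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (length(gr)) {
    attrs <- paste0("ID=", mcols(gr)$gene_id,
                    ifelse(nzchar(mcols(gr)$product),
                           paste0(";product=", mcols(gr)$product), ""))
    writeLines(paste(as.character(seqnames(gr)), source, "CDS",
                     start(gr), end(gr), ".", as.character(strand(gr)), ".",
                     attrs, sep = "\t"), con)
  }
  invisible(path)
}

knownPhyla <- function() c("Actinomycetota", "Bacillota", "Bacillota_A")

#' Read or write a taxonomy table
#'
#' Tab-separated taxonomy with header \code{id}, \code{phylum}, \code{genus},
#' \code{species}; empty fields are allowed but a non-empty phylum must come
#' from the controlled vocabulary (Actinomycetota, Bacillota, Bacillota_A).
#'
#' @param path File path.
#' @return \code{readTaxonomy}: a data.frame with the four columns.
#' @export
readTaxonomy <- function(path) {
  tab <- utils::read.delim(path, colClasses = "character")
  need <- c("id", "phylum", "genus", "species")
  if (!all(need %in% names(tab)))
    stop("taxonomy table must have columns: ", paste(need, collapse = ", "))
  if (any(!nzchar(tab$id))) stop("taxonomy row with empty id")
  if (anyDuplicated(tab$id)) stop("duplicate taxonomy id")
  badPhy <- nzchar(tab$phylum) & !tab$phylum %in% knownPhyla()
  if (any(badPhy))
    stop("unknown phylum: ", tab$phylum[badPhy][1L])
  tab[need]
}

#' @rdname readTaxonomy
#' @param tax data.frame as returned by \code{readTaxonomy}.
#' @export
writeTaxonomy <- function(tax, path) {
  utils::write.table(tax, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
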