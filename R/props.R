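checkCanonical <- function(seq, what) {
  if (!nzchar(seq)) stop(what, " requires a non-empty sequence")
  bad <- regexpr(paste0("[^", paste0(aminoAcids(), collapse = ""), "]"), seq)
  if (bad > 0L)
    stop(what, " requires canonical residues only; found '",
         substr(seq, bad, bad), "' at position ", bad)
  invisible(seq)
}

#' GRAVY hydropathy
#'
#' Grand average of hydropathy: the mean Kyte-Doolittle value over all
#' residues. Sequences containing X are rejected since an unknown residue
#' has no hydropathy value.
#'
#' @param seq Sequence (AAStringSet of 1, AAString or character).
#' @return Mean hydropathy in [-4.5, 4.5].
#' @export
#' @examples
#' gravy("I")   # 4.5
#' gravy("IR")  # 0
gravy <- function(seq) {
  s <- asSequenceString(seq)
  checkCanonical(s, "gravy")
  mean(kyteDoolittle()[strsplit(s, "", fixed = TRUE)[[1L]]])
}

#' Average molecular weight
#'
#' Sum of average residue masses plus one water (18.0153 Da).
#'
#' @inheritParams gravy
#' @return Mass in daltons.
#' @export
#' @examples
#' molecularWeight("G")  # free glycine, ~75.07 Da
molecularWeight <- function(seq) {
  s <- asSequenceString(seq)
  checkCanonical(s, "molecularWeight")
  sum(residueMasses()[strsplit(s, "", fixed = TRUE)[[1L]]]) + waterMass()
}

#' Henderson-Hasselbalch net charge
#'
#' Positive terms (N-terminus, K, R, H): \code{1 / (1 + 10^(pH - pK))};
#' negative terms (C-terminus, D, E, C, Y): \code{-1 / (1 + 10^(pK - pH))}.
#' The packaged default pK scale is EMBOSS ([embossPk()]).
#'
#' @inheritParams gravy
#' @param pH pH in [0, 14] (default 7).
#' @param pk Named pK table with entries Nterm, Cterm, K, R, H, D, E, C, Y.
#' @return Net charge in elementary charges; strictly decreasing in pH.
#' @export
netCharge <- function(seq, pH = 7, pk = embossPk()) {
  if (pH < 0 || pH > 14) stop("pH must lie in [0, 14]")
  s <- asSequenceString(seq)
  checkCanonical(s, "netCharge")
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- table(factor(chars, levels = c("K", "R", "H", "D", "E", "C", "Y")))
  pos <- c(Nterm = 1, n[c("K", "R", "H")])
  neg <- c(Cterm = 1, n[c("D", "E", "C", "Y")])
  posPk <- pk[c("Nterm", "K", "R", "H")]
  negPk <- pk[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - posPk))) - sum(neg / (1 + 10^(negPk - pH)))
}

#' Isoelectric point by bisection
#'
#' The pH at which [netCharge()] is zero, found by bisection on [0, 14].
#' The interval is narrowed to 1e-6 pH units so the residual charge at the
#' reported pI is far below 1e-3 elementary charges even for long peptides.
#' If the charge has the same sign at both ends of the scale the boundary
#' value is returned with attribute \code{boundary = TRUE}.
#'
#' @inheritParams netCharge
#' @return pI in pH units.
#' @export
isoelectricPoint <- function(seq, pk = embossPk()) {
  s <- asSequenceString(seq)
  checkCanonical(s, "isoelectricPoint")
  lo <- 0; hi <- 14
  cLo <- netCharge(s, lo, pk); cHi <- netCharge(s, hi, pk)
  if (sign(cLo) == sign(cHi)) {
    out <- if (cLo > 0) hi else lo
    attr(out, "boundary") <- TRUE
    return(out)
  }
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (sign(netCharge(s, mid, pk)) == sign(cLo)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Convert a mass dose to molar concentration
#'
#' \code{(dose in ug/mL) / (MW in Da) * 1000} micromolar — the arithmetic
#' behind reporting a 100 ug/mL well-diffusion dose of a 6.3 kDa peptide as
#' 15.9 uM.
#'
#' @param doseUgPerMl Dose in micrograms per milliliter (> 0).
#' @param mwDa Molecular weight in daltons (> 0).
#' @return Concentration in micromolar, to 1 decimal.
#' @export
#' @examples
#' doseToMolar(100, 6300)  # 15.9
doseToMolar <- function(doseUgPerMl, mwDa) {
  if (doseUgPerMl <= 0 || mwDa <= 0)
    stop("dose and molecular weight must be positive")
  round(doseUgPerMl / mwDa * 1000, 1)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square upper-tail p-value
#' (df = groups - 1), computed by [stats::kruskal.test()]. If all values are
#' identical, H = 0 and p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length; >= 2 non-empty groups.
#' @return List with \code{H}, \code{df}, \code{p}.
#' @export
#' @examples
#' kruskalWallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
kruskalWallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")
  if (length(values) < 3L) stop("need at least 3 observations in total")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Physicochemical property table of core peptides
#'
#' @param records Named AAStringSet.
#' @param pH pH at which net charge is reported (default 7).
#' @return data.frame with id, length, gravy, mw, charge, pI.
#' @export
peptideProperties <- function(records, pH = 7) {
  seqs <- as.character(records)
  data.frame(
    id = names(records),
    length = unname(nchar(seqs)),
    gravy = vapply(seqs, gravy, numeric(1L), USE.NAMES = FALSE),
    mw = vapply(seqs, molecularWeight, numeric(1L), USE.NAMES = FALSE),
    charge = vapply(seqs, netCharge, numeric(1L), pH = pH, USE.NAMES = FALSE),
    pI = vapply(seqs, function(s) as.numeric(isoelectricPoint(s)),
                numeric(1L), USE.NAMES = FALSE))
}

#' Per-property phylum contrast
#'
#' Runs [kruskalWallis()] on each property column of [peptideProperties()]
#' output, grouped by phylum.
#'
#' @param props data.frame from [peptideProperties()].
#' @param phylum Named vector mapping id to phylum.
#' @return data.frame with property, H, df, p.
#' @export
propertyContrast <- function(props, phylum) {
  grp <- unname(phylum[props$id])
  cols <- c("length", "gravy", "mw", "charge", "pI")
  res <- lapply(cols, function(cl) {
    kt <- kruskalWallis(props[[cl]], grp)
    data.frame(property = cl, H = kt$H, df = kt$df, p = kt$p)
  })
  do.call(rbind, res)
}
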