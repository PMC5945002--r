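# Monoisotopic mass and halogen isotopologue utilities: the computational
# counterpart of verifying a halogenated product (e.g. 3-bromoindole) by
# mass spectrometry.

# Embedded isotope table: monoisotopic masses (Da) of the most abundant
# isotope for common elements, plus the halogen isotopes with their natural
# abundances. Values are CODATA/IUPAC standard atomic masses.
ISOTOPE_MASSES <- list(
  H  = c(`1` = 1.00782503207),
  C  = c(`12` = 12.0),
  N  = c(`14` = 14.0030740048),
  O  = c(`16` = 15.99491461956),
  S  = c(`32` = 31.97207100),
  P  = c(`31` = 30.97376163),
  F  = c(`19` = 18.99840322),
  I  = c(`127` = 126.904473),
  Cl = c(`35` = 34.96885268, `37` = 36.96590259),
  Br = c(`79` = 78.9183371, `81` = 80.9162906)
)

HALOGEN_ABUNDANCES <- list(
  Cl = c(`35` = 0.7576, `37` = 0.2424),
  Br = c(`79` = 0.5069, `81` = 0.4931)
)

#' Parse a Hill-notation molecular formula
#'
#' @param formula A string such as `"C8H6BrN"`.
#' @return A named integer vector of element counts.
#' @export
#' @examples
#' parseFormula("C8H6BrN")
parseFormula <- function(formula) {
  s <- gsub("[[:space:]]", "", formula)
  if (length(s) == 0L || !nzchar(s))
    return(setNames(integer(0), character(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1L]]
  toks <- regmatches(s, list(m))[[1L]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula: ", formula)
  el <- sub("[0-9]*$", "", toks)
  ct <- sub("^[A-Z][a-z]?", "", toks)
  ct <- ifelse(nzchar(ct), as.integer(ct), 1L)
  out <- tapply(ct, el, sum)
  setNames(as.integer(out), names(out))
}

#' Neutral monoisotopic mass of a molecular formula
#'
#' Sums the chosen isotope masses from the embedded table: most abundant
#' isotope by default, with an explicit isotope choice for halogens (and any
#' other tabulated element). The neutral-molecule convention is used with no
#' proton or electron adjustment; display rounding is conventionally three
#' decimals, half-up (see [roundHalfUp()]).
#'
#' @param formula Named element counts (as from [parseFormula()]) or a
#'   formula string.
#' @param isotopes Optional named vector choosing isotopes by mass number,
#'   e.g. `c(Br = 79)`.
#' @return Mass in Da (full double precision).
#' @export
#' @examples
#' roundHalfUp(monoisotopicMass("C8H6BrN", c(Br = 79)), 3)  # 3-bromoindole
monoisotopicMass <- function(formula, isotopes = NULL) {
  if (is.character(formula)) formula <- parseFormula(formula)
  if (length(formula) == 0L) return(0)
  mass <- 0
  for (el in names(formula)) {
    tab <- ISOTOPE_MASSES[[el]]
    if (is.null(tab)) stop("unknown element symbol: ", el)
    if (!is.null(isotopes) && el %in% names(isotopes)) {
      key <- as.character(isotopes[[el]])
      if (!key %in% names(tab))
        stop("no isotope ", key, " tabulated for ", el)
      m1 <- tab[[key]]
    } else {
      m1 <- tab[[1L]]  # most abundant isotope listed first
    }
    mass <- mass + formula[[el]] * m1
  }
  mass
}

#' Round half-up to a fixed number of decimals
#'
#' Display convention for reported masses (R's `round` uses banker's
#' rounding, which is not how printed masses are conventionally rounded).
#'
#' @param x Numeric.
#' @param digits Number of decimals.
#' @return Numeric.
#' @export
roundHalfUp <- function(x, digits = 3L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Halogen isotopologue pattern of a molecular formula
#'
#' Enumerates every Cl/Br isotope assignment of the formula, collapses
#' assignments of equal heavy-isotope count (mass degeneracy), and returns
#' the peaks sorted by mass with natural-abundance weights that sum to one.
#' A mono-bromo compound yields the characteristic near-1:1 doublet split by
#' about 1.998 Da; a halogen-free compound yields a single peak.
#'
#' @inheritParams monoisotopicMass
#' @return A data.frame with columns `mass` (Da) and `rel_abundance`.
#' @export
#' @examples
#' halogenPattern("C8H6BrN")
halogenPattern <- function(formula) {
  if (is.character(formula)) formula <- parseFormula(formula)
  halos <- intersect(names(HALOGEN_ABUNDANCES), names(formula))
  base <- formula[setdiff(names(formula), halos)]
  base_mass <- if (length(base)) monoisotopicMass(base) else 0
  peaks <- data.frame(mass = base_mass, rel_abundance = 1)
  for (el in halos) {
    nAtoms <- formula[[el]]
    ab <- HALOGEN_ABUNDANCES[[el]]
    masses <- ISOTOPE_MASSES[[el]]
    k <- 0:nAtoms  # number of heavy-isotope atoms
    w <- stats::dbinom(k, nAtoms, ab[[2L]])
    dm <- k * masses[[2L]] + (nAtoms - k) * masses[[1L]]
    peaks <- do.call(rbind, lapply(seq_along(k), function(i) {
      data.frame(mass = peaks$mass + dm[i],
                 rel_abundance = peaks$rel_abundance * w[i])
    }))
  }
  peaks <- stats::aggregate(rel_abundance ~ mass, peaks, sum)
  peaks <- peaks[order(peaks$mass), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks
}
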