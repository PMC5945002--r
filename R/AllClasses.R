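# S4 classes for the profile-HMM machinery.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Gumbel calibration of a profile HMM score distribution
#'
#' Holds the location/scale of a Gumbel (type-I extreme value) distribution
#' fitted by maximum likelihood to Forward bit scores of i.i.d. background
#' decoy sequences, together with the provenance of the fit. E-values derived
#' from this fit are specific to this package's scorer and are not
#' numerically comparable to HMMER3 E-values.
#'
#' @slot mu Gumbel location parameter (bits).
#' @slot lambda Gumbel scale parameter (1/bits), strictly positive.
#' @slot nDecoys Number of decoy sequences scored.
#' @slot decoyLength Length of each decoy (residues).
#' @slot seed Integer seed the decoys were drawn with.
#' @export
setClass("GumbelFit",
  representation(mu = "numeric", lambda = "numeric",
                 nDecoys = "integer", decoyLength = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@mu) != 1L || !is.finite(object@mu))
      return("mu must be a finite scalar")
    if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
        object@lambda <= 0)
      return("lambda must be a positive finite scalar")
    if (object@nDecoys < 100L)
      return("nDecoys must be >= 100")
    TRUE
  })

setClassUnion("GumbelFitOrNULL", c("GumbelFit", "NULL"))

#' Profile hidden Markov model of a protein family
#'
#' A minimal Plan7-style profile HMM with match, insert and delete states,
#' shared insert emissions, an embedded background residue distribution, and
#' an optional Gumbel score calibration. Scoring uses a single-hit local
#' alignment architecture: an alignment fragment enters at any match state
#' and leaves from any later match state with a uniform fragment prior, and
#' flanking residues are free under the null model.
#'
#' @slot L Number of match states.
#' @slot matchEmit `L x 20` matrix of match emission probabilities
#'   (columns in canonical residue order); rows sum to 1.
#' @slot insertEmit Length-20 insert emission distribution shared by all
#'   insert states.
#' @slot trans `(L+1) x 7` matrix of core transition probabilities with
#'   columns `mm, mi, md, im, ii, dm, dd`. Row `k` (rowname `"k"`, 0-based)
#'   holds transitions out of position-`k` states into position `k+1`;
#'   row 0 is the begin state (`mm` = B->M1, `md` = B->D1).
#' @slot background Length-20 background residue distribution.
#' @slot calibration A [GumbelFit-class] or `NULL` if uncalibrated.
#' @slot refMap Named list of integer vectors: for each training-alignment
#'   row retained as a reference, the map from its residue positions to match
#'   columns (0 where a residue fell in an insert column). Used to anchor
#'   catalytic-residue mapping.
#' @slot name Model name.
#' @export
setClass("ProfileHMM",
  representation(L = "integer", matchEmit = "matrix", insertEmit = "numeric",
                 trans = "matrix", background = "numeric",
                 calibration = "GumbelFitOrNULL", refMap = "list",
                 name = "character"),
  validity = function(object) {
    L <- object@L
    if (L < 1L) return("L must be >= 1")
    if (!all(dim(object@matchEmit) == c(L, 20L)))
      return("matchEmit must be L x 20")
    tol <- 1e-9
    if (any(abs(rowSums(object@matchEmit) - 1) > tol))
      return("match emission rows must each sum to 1")
    if (abs(sum(object@insertEmit) - 1) > tol)
      return("insert emission vector must sum to 1")
    if (abs(sum(object@background) - 1) > tol)
      return("background vector must sum to 1")
    tr <- object@trans
    if (!all(dim(tr) == c(L + 1L, 7L)))
      return("trans must be (L+1) x 7")
    need <- c("mm", "mi", "md", "im", "ii", "dm", "dd")
    if (!identical(colnames(tr), need))
      return("trans columns must be mm, mi, md, im, ii, dm, dd")
    if (abs(sum(tr[1L, c("mm", "md")]) - 1) > tol)
      return("begin bundle (row 0) must have mm + md = 1")
    if (L > 1L) {
      core <- tr[2:L, , drop = FALSE]
      if (any(abs(rowSums(core[, c("mm", "mi", "md"), drop = FALSE]) - 1) > tol))
        return("match transition bundles must sum to 1")
      if (any(abs(rowSums(core[, c("im", "ii"), drop = FALSE]) - 1) > tol))
        return("insert transition bundles must sum to 1")
      if (any(abs(rowSums(core[, c("dm", "dd"), drop = FALSE]) - 1) > tol))
        return("delete transition bundles must sum to 1")
    }
    TRUE
  })

#' @describeIn ProfileHMM-class Number of match states.
#' @param x,object A `ProfileHMM`.
#' @export
hmmLength <- function(x) x@L

#' @describeIn ProfileHMM-class Match emission probability matrix.
#' @export
matchEmissions <- function(x) x@matchEmit

#' @describeIn ProfileHMM-class Shared insert emission distribution.
#' @export
insertEmissions <- function(x) x@insertEmit

#' @describeIn ProfileHMM-class Core transition probability matrix.
#' @export
transitionProbs <- function(x) x@trans

#' @describeIn ProfileHMM-class Background residue distribution.
#' @export
backgroundFreqs <- function(x) x@background

#' @describeIn ProfileHMM-class Gumbel calibration (or `NULL`).
#' @export
calibration <- function(x) x@calibration

#' @describeIn ProfileHMM-class Replace the calibration.
#' @param value A [GumbelFit-class].
#' @export
`calibration<-` <- function(x, value) {
  x@calibration <- value
  validObject(x)
  x
}

setMethod("show", "ProfileHMM", function(object) {
  cat("ProfileHMM", if (nzchar(object@name)) sQuote(object@name) else "",
      "with", object@L, "match states\n")
  cat("  calibrated:", if (is.null(object@calibration)) "no" else "yes", "\n")
  if (length(object@refMap))
    cat("  reference maps:", paste(names(object@refMap), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "GumbelFit", function(object) {
  cat(sprintf("GumbelFit: mu = %.3f bits, lambda = %.4f (n = %d decoys of length %d, seed %d)\n",
              object@mu, object@lambda, object@nDecoys, object@decoyLength,
              object@seed))
  invisible(object)
})
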