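# Distance phylogenetics (p-distance, neighbour joining, bootstrap) and
# variant A/B classification of candidate halogenases.

.msa_codes <- function(msa) {
  m <- if (is.matrix(msa)) msa else msaMatrix(msa)
  codes <- matrix(match(m, AA20, nomatch = 0L), nrow(m), ncol(m))
  codes[m == "X"] <- 0L   # ambiguous residues excluded pairwise
  rownames(codes) <- rownames(m)
  codes
}

#' Pairwise p-distance matrix from a protein alignment
#'
#' The proportion of differing residues over columns where both sequences
#' carry a residue (pairwise deletion of gapped columns, which preserves
#' signal on partial-length candidates). The optional Poisson correction
#' `-ln(1 - p)` accounts for multiple substitutions.
#'
#' @param msa Equal-width gapped [Biostrings::AAStringSet] (or character
#'   matrix) with at least 3 rows.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @return A symmetric numeric matrix with zero diagonal, taxa as dimnames.
#' @export
pDistanceMatrix <- function(msa, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  codes <- .msa_codes(msa)
  n <- nrow(codes)
  if (n < 3L) stop("need at least 3 sequences")
  ids <- rownames(codes)
  nz <- codes > 0L
  comparable <- tcrossprod(nz * 1L)           # columns with residues in both
  matches <- matrix(0, n, n)
  for (a in 1:20) {
    ia <- (codes == a) * 1L
    matches <- matches + tcrossprod(ia)
  }
  if (any(comparable[upper.tri(comparable)] == 0L)) {
    idx <- which(comparable == 0L & upper.tri(comparable), arr.ind = TRUE)[1L, ]
    stop("no comparable columns between ", ids[idx[1L]], " and ", ids[idx[2L]])
  }
  p <- 1 - matches / comparable
  if (correction == "poisson") {
    if (any(p[upper.tri(p)] >= 1))
      stop("saturated distance (p = 1): Poisson correction undefined")
    p <- -log(1 - p)
  }
  diag(p) <- 0
  dimnames(p) <- list(ids, ids)
  p
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via [ape::nj()]); negative branch lengths,
#' which NJ can produce on non-additive inputs, are clamped to zero with a
#' message. On an additive distance matrix the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param d Symmetric nonnegative matrix with zero diagonal and taxa
#'   dimnames.
#' @return An unrooted [ape::phylo] tree.
#' @export
njTree <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(!is.finite(d))) stop("distances must be finite")
  tree <- ape::nj(d)
  if (any(tree$edge.length < 0)) {
    message(sum(tree$edge.length < 0),
            " negative NJ branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Classic Felsenstein procedure: alignment columns are resampled with
#' replacement `nReps` times (default 1000 replicates), a NJ tree is built
#' per replicate, and each internal edge of the full-data tree is labelled
#' with the percentage of replicate trees containing its bipartition.
#' Replicates leaving some pair with no comparable columns are redrawn
#' (counted, capped at `10 * nReps`).
#'
#' @inheritParams pDistanceMatrix
#' @param nReps Number of bootstrap replicates; default 1000.
#' @param seed Integer seed for resampling.
#' @return The full-data [ape::phylo] tree with integer percentage supports
#'   in `node.label` (root label empty).
#' @export
bootstrapSupport <- function(msa, nReps = 1000L, seed = defaultSeed(),
                             correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  if (nReps < 1L) stop("nReps must be >= 1")
  m <- if (is.matrix(msa)) msa else msaMatrix(msa)
  full <- njTree(pDistanceMatrix(m, correction))
  nc <- ncol(m)
  boots <- .with_seed(seed, {
    out <- vector("list", nReps)
    attempts <- 0L; i <- 1L
    while (i <= nReps) {
      attempts <- attempts + 1L
      if (attempts > 10L * nReps)
        stop("too many degenerate bootstrap replicates")
      cols <- sample.int(nc, nc, replace = TRUE)
      tr <- tryCatch(njTree(pDistanceMatrix(m[, cols, drop = FALSE],
                                            correction)),
                     error = function(e) NULL)
      if (is.null(tr)) next
      out[[i]] <- tr; i <- i + 1L
    }
    out
  })
  class(boots) <- "multiPhylo"
  counts <- suppressWarnings(ape::prop.clades(full, boots, rooted = FALSE))
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / nReps))
  full$node.label <- as.character(support)
  full$node.label[1L] <- ""  # root of the unrooted representation
  full
}

#' Classify a candidate halogenase as variant A or B
#'
#' Finds the smallest bipartition side of the tree that contains the query
#' together with reference halogenases of exactly one class; the candidate
#' inherits that class (evidence `"clade"`). When every such side is mixed,
#' the call falls back to a length prior: variant B halogenases run about
#' `deltaAa` (70 by default) residues shorter than variant A, so the query
#' is assigned to whichever class mean reference length it is closer to
#' (evidence `"length_prior"`). Without usable clade or length evidence the
#' candidate stays unclassified.
#'
#' @param tree An [ape::phylo] containing the query and at least 2
#'   references per class.
#' @param refsA,refsB Character vectors of reference tip labels.
#' @param query Query tip label.
#' @param queryLength Optional query protein length (residues) for the
#'   length prior.
#' @param refLengths Optional named numeric vector of reference protein
#'   lengths (residues) used by the length prior.
#' @param deltaAa Expected A-minus-B length difference; default 70.
#' @return A one-row data.frame: `query`, `call` (`"A"`, `"B"` or
#'   `"unclassified"`), `evidence` (`"clade"`, `"length_prior"` or `NA`),
#'   `nearest_ref`.
#' @export
classifyVariant <- function(tree, refsA, refsB, query, queryLength = NULL,
                            refLengths = NULL, deltaAa = 70) {
  stopifnot(inherits(tree, "phylo"))
  if (deltaAa <= 0) stop("deltaAa must be positive")
  tips <- tree$tip.label
  if (!query %in% tips) stop("query ", query, " absent from tree")
  refsA <- intersect(refsA, tips); refsB <- intersect(refsB, tips)
  if (length(refsA) < 2L || length(refsB) < 2L)
    stop("need at least 2 references per class in the tree")
  # duplicate-taxon shortcut: zero distance to a reference decides directly
  coph <- ape::cophenetic.phylo(tree)
  dq <- coph[query, c(refsA, refsB)]
  nearest <- names(dq)[which.min(dq)]
  parts <- ape::prop.part(tree)
  sides <- list()
  for (p in parts) {
    sides[[length(sides) + 1L]] <- tips[p]
    sides[[length(sides) + 1L]] <- setdiff(tips, tips[p])
  }
  best_size <- Inf; best_class <- NULL
  for (side in sides) {
    if (!query %in% side) next
    nA <- sum(refsA %in% side); nB <- sum(refsB %in% side)
    if (nA + nB == 0L) next
    pure <- xor(nA > 0L, nB > 0L)
    if (pure && length(side) < best_size) {
      best_size <- length(side)
      best_class <- if (nA > 0L) "A" else "B"
    }
  }
  if (!is.null(best_class))
    return(data.frame(query = query, call = best_class, evidence = "clade",
                      nearest_ref = nearest, stringsAsFactors = FALSE))
  if (!is.null(queryLength) && !is.null(refLengths)) {
    mA <- mean(refLengths[names(refLengths) %in% refsA])
    mB <- mean(refLengths[names(refLengths) %in% refsB])
    if (is.finite(mA) && is.finite(mB)) {
      call <- if (abs(queryLength - mA) <= abs(queryLength - mB)) "A" else "B"
      return(data.frame(query = query, call = call,
                        evidence = "length_prior", nearest_ref = nearest,
                        stringsAsFactors = FALSE))
    }
  }
  data.frame(query = query, call = "unclassified", evidence = NA_character_,
             nearest_ref = nearest, stringsAsFactors = FALSE)
}
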