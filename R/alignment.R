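# Pairwise local alignment, threshold-based homolog collection, and a
# progressive multiple aligner used to expand a seed set of characterised
# halogenases before HMM construction.

.check_protein <- function(x, what = "sequence") {
  bad <- regexpr(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("unknown residue '%s' in %s %d",
                 substr(x[i], bad[i], bad[i]), what, i))
  }
  invisible(TRUE)
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman alignment with affine gaps under BLOSUM62 (BLAST
#' protein defaults: gap open 11, extend 1), computed with
#' [Biostrings::pairwiseAlignment()]. Identity is the fraction of identical
#' columns over all alignment columns (gaps included); query coverage is the
#' fraction of query residues inside the aligned region.
#'
#' @param query,target Protein sequences (character scalars, `AAString`s, or
#'   length-1 `AAStringSet`s). `query` should be the characterised reference
#'   when thresholds are interpreted as "identity to / coverage of" it.
#' @param gapOpen,gapExtend Positive gap penalties.
#' @return A list with elements `query_id`, `target_id`, `aligned_query`,
#'   `aligned_target`, `score`, `identity`, `query_coverage`.
#' @export
localAlign <- function(query, target, gapOpen = 11, gapExtend = 1) {
  qid <- names(query)[1L] %||% "query"
  tid <- names(target)[1L] %||% "target"
  q <- toupper(as.character(query))[1L]
  t <- toupper(as.character(target))[1L]
  if (!nzchar(q) || !nzchar(t)) stop("sequences must be non-empty")
  .check_protein(c(q, t))
  if (gapOpen <= 0 || gapExtend <= 0) stop("gap penalties must be positive")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(q), subject = Biostrings::AAString(t),
    type = "local", substitutionMatrix = blosum62full(),
    gapOpening = gapOpen, gapExtension = gapExtend)
  aq <- as.character(Biostrings::alignedPattern(aln))
  at <- as.character(Biostrings::alignedSubject(aln))
  qc <- strsplit(aq, "")[[1L]]
  tc <- strsplit(at, "")[[1L]]
  ncol <- length(qc)
  ident <- if (ncol) sum(qc == tc & qc != "-") / ncol else 0
  cov <- if (ncol) sum(qc != "-") / nchar(q) else 0
  list(query_id = qid, target_id = tid,
       aligned_query = aq, aligned_target = at,
       score = Biostrings::score(aln), identity = ident,
       query_coverage = cov)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a) || !nzchar(a)) b else a

#' Collect close homologs of reference halogenases from a database
#'
#' A database record is retained when, for at least one reference, local
#' alignment identity and reference (query) coverage both reach their
#' thresholds — the 50% identity / 90% coverage rule used to expand a seed
#' set of characterised FHals before profile construction. Output is
#' deduplicated by id with input order preserved.
#'
#' @param refs Non-empty [Biostrings::AAStringSet] of characterised proteins.
#' @param database [Biostrings::AAStringSet] to screen.
#' @param idThreshold,covThreshold Fractions in `[0, 1]`; defaults 0.50
#'   and 0.90.
#' @inheritParams localAlign
#' @return The retained subset of `database`.
#' @export
collectHomologs <- function(refs, database, idThreshold = 0.50,
                            covThreshold = 0.90, gapOpen = 11,
                            gapExtend = 1) {
  if (length(refs) == 0L) stop("refs must be non-empty")
  if (idThreshold < 0 || idThreshold > 1 || covThreshold < 0 || covThreshold > 1)
    stop("thresholds must lie in [0, 1]")
  if (length(database) == 0L) return(database)
  keep <- vapply(seq_along(database), function(j) {
    for (i in seq_along(refs)) {
      al <- localAlign(refs[i], database[j], gapOpen, gapExtend)
      if (al$identity >= idThreshold && al$query_coverage >= covThreshold)
        return(TRUE)
    }
    FALSE
  }, logical(1))
  res <- database[keep]
  res[!duplicated(names(res))]
}

# 3-mer count vector distance between ungapped sequences: one minus the
# fraction of shared k-mer counts relative to the shorter sequence
.kmer_dist <- function(seqs, k = 3L) {
  counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(table(character(0)))
    table(substring(s, 1:(n - k + 1L), k:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ci <- counts[[i]]; cj <- counts[[j]]
    shared <- intersect(names(ci), names(cj))
    common <- sum(pmin(ci[shared], cj[shared]))
    denom <- max(1L, min(nchar(seqs[i]), nchar(seqs[j])) - k + 1L)
    d[i, j] <- d[j, i] <- 1 - common / denom
  }
  d
}

.profile_of <- function(rows) {
  # rows: character vector of equal-length gapped strings -> 20 x ncol
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  nc <- ncol(m)
  p <- matrix(0, 20L, nc, dimnames = list(AA20, NULL))
  nr <- nrow(m)
  for (a in seq_along(AA20))
    p[a, ] <- colSums(m == AA20[a]) / nr
  p
}

#' Progressive multiple alignment of protein sequences
#'
#' A single progressive pass: a UPGMA guide tree is built from 3-mer
#' count-vector distances, then profiles are merged leaf-to-root by global
#' profile-profile alignment with sum-of-pairs BLOSUM62 scoring and affine
#' gaps. No iterative refinement is performed; downstream profile-HMM
#' quality, not alignment aesthetics, is what the pipeline depends on.
#'
#' @param seqs An [Biostrings::AAStringSet] (>= 2 sequences for a true
#'   alignment; a single sequence is returned as a degenerate one-row
#'   alignment with a warning).
#' @param gapOpen,gapExtend Positive affine gap penalties.
#' @return An equal-width gapped [Biostrings::AAStringSet], rows in input
#'   order; de-gapping any row restores the corresponding input exactly.
#' @export
progressiveMsa <- function(seqs, gapOpen = 11, gapExtend = 1) {
  ids <- names(seqs)
  ch <- toupper(as.character(seqs))
  .check_protein(ch)
  n <- length(ch)
  if (n == 0L) stop("no sequences")
  if (n == 1L) {
    warning("single sequence: returning a degenerate one-row alignment")
    out <- Biostrings::AAStringSet(ch)
    names(out) <- ids
    return(out)
  }
  if (is.null(ids) || anyDuplicated(ids)) stop("sequences must carry unique names")
  sub <- blosum62()
  if (n == 2L) {
    merged <- .merge_profiles(list(rows = ch[1L], ids = ids[1L]),
                              list(rows = ch[2L], ids = ids[2L]),
                              sub, gapOpen, gapExtend)
  } else {
    d <- .kmer_dist(ch)
    hc <- stats::hclust(stats::as.dist(d), method = "average")  # UPGMA
    clusters <- lapply(seq_len(n), function(i) list(rows = ch[i], ids = ids[i]))
    merged_list <- vector("list", nrow(hc$merge))
    for (s in seq_len(nrow(hc$merge))) {
      pick <- function(idx) if (idx < 0) clusters[[-idx]] else merged_list[[idx]]
      merged_list[[s]] <- .merge_profiles(pick(hc$merge[s, 1L]),
                                          pick(hc$merge[s, 2L]),
                                          sub, gapOpen, gapExtend)
    }
    merged <- merged_list[[nrow(hc$merge)]]
  }
  ord <- match(ids, merged$ids)
  out <- Biostrings::AAStringSet(merged$rows[ord])
  names(out) <- ids
  out
}

.merge_profiles <- function(a, b, sub, gapOpen, gapExtend) {
  pa <- .profile_of(a$rows)
  pb <- .profile_of(b$rows)
  al <- .profile_align(pa, pb, sub, gapOpen, gapExtend)
  adva <- al$advance_a; advb <- al$advance_b
  expand <- function(rows, adv) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    outm <- matrix("-", nrow(m), length(adv))
    outm[, adv == 1L] <- m
    apply(outm, 1L, paste, collapse = "")
  }
  list(rows = c(expand(a$rows, adva), expand(b$rows, advb)),
       ids = c(a$ids, b$ids))
}
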