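# Independent brute-force oracles and small fixture builders shared across
# the suite. Each oracle is a deliberately naive implementation kept separate
# from the package's algorithms.

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# -- profile-HMM path enumeration ------------------------------------------
# Explicit sum/max over every state path of the single-hit local fragment
# architecture (entry prior 2 / (L(L+1)), free flanks, exit from match).
enum_paths <- function(hmm, seq, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  L <- hmmLength(hmm); tr <- transitionProbs(hmm)
  me <- matchEmissions(hmm); ie <- insertEmissions(hmm)
  bg <- backgroundFreqs(hmm)
  x <- match(strsplit(seq, "")[[1]], AA)
  n <- length(x)
  emo <- function(k, i) me[k, x[i]] / bg[x[i]]
  ino <- function(i) ie[x[i]] / bg[x[i]]
  acc <- if (mode == "sum") 0 else -Inf
  comb <- function(a, b) if (mode == "sum") a + b else max(a, b)
  rec <- function(state, k, i, w) {
    if (state == "M") {
      acc <<- comb(acc, w)
      if (k < L) {
        if (i < n) rec("M", k + 1, i + 1, w * tr[k + 1, "mm"] * emo(k + 1, i + 1))
        if (i < n) rec("I", k, i + 1, w * tr[k + 1, "mi"] * ino(i + 1))
        rec("D", k + 1, i, w * tr[k + 1, "md"])
      }
    } else if (state == "I") {
      if (i < n) rec("M", k + 1, i + 1, w * tr[k + 1, "im"] * emo(k + 1, i + 1))
      if (i < n) rec("I", k, i + 1, w * tr[k + 1, "ii"] * ino(i + 1))
    } else {
      if (k < L) {
        if (i < n) rec("M", k + 1, i + 1, w * tr[k + 1, "dm"] * emo(k + 1, i + 1))
        rec("D", k + 1, i, w * tr[k + 1, "dd"])
      }
    }
  }
  entry <- 2 / (L * (L + 1))
  for (i in seq_len(n)) for (k in seq_len(L)) rec("M", k, i, entry * emo(k, i))
  unname(log2(acc))
}

# random tiny HMM built from a random gapped alignment; NULL if the build
# degenerates or exceeds the requested size
random_tiny_hmm <- function(max_L = 3) {
  nr <- sample(2:4, 1); nc <- sample(2:5, 1)
  rows <- replicate(nr, paste(sample(AA, nc, replace = TRUE), collapse = ""))
  rows <- vapply(rows, function(r) {
    p <- sample(nc, 1)
    if (runif(1) < 0.3) substr(r, p, p) <- "-"
    r
  }, "")
  msa <- Biostrings::AAStringSet(setNames(rows, paste0("s", seq_len(nr))))
  h <- tryCatch(buildHmm(msa), error = function(e) NULL)
  if (!is.null(h) && hmmLength(h) > max_L) return(NULL)
  h
}

# one-match-state model emitting a single residue surely, uniform background
unit_hmm <- function(residue = "K") {
  em <- matrix(0, 1, 20, dimnames = list(NULL, AA))
  em[1, residue] <- 1
  tr <- matrix(0, 2, 7, dimnames = list(0:1, c("mm", "mi", "md", "im", "ii",
                                               "dm", "dd")))
  tr[1, "mm"] <- 1; tr[1, c("im", "dm")] <- 1
  tr[2, ] <- c(1, 0, 0, 1, 0, 1, 0)
  new("ProfileHMM", L = 1L, matchEmit = em,
      insertEmit = setNames(rep(1 / 20, 20), AA), trans = tr,
      background = setNames(rep(1 / 20, 20), AA),
      calibration = NULL, refMap = list(), name = "unit")
}

# -- brute-force Smith-Waterman --------------------------------------------
# Enumerates every monotone set of matched residue pairs between the two
# sequences; internal gaps cost gapOpen + gapExt * length (BLAST convention).
brute_sw <- function(q, t, sub, gapOpen = 11, gapExt = 1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  n <- length(qc); m <- length(tc)
  best <- 0
  gap_cost <- function(len) if (len > 0) gapOpen + gapExt * len else 0
  rec <- function(i, j, score) {
    best <<- max(best, score)
    if (i > n || j > m) return()
    for (ii in i:n) for (jj in j:m) {
      s <- score + sub[qc[ii], tc[jj]] -
        gap_cost(ii - i) - gap_cost(jj - j)
      rec(ii + 1, jj + 1, s)
    }
  }
  for (i in seq_len(n)) for (j in seq_len(m))
    rec(i + 1, j + 1, sub[qc[i], tc[j]])
  best
}

# -- naive motif scanner ----------------------------------------------------
naive_motif_scan <- function(seq, pattern) {
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(seq, "")[[1]]
  w <- length(pc)
  hits <- integer(0)
  if (length(sc) >= w) for (s in 1:(length(sc) - w + 1)) {
    ok <- TRUE
    for (p in seq_len(w))
      if (pc[p] != "x" && sc[s + p - 1] != pc[p]) { ok <- FALSE; break }
    if (ok) hits <- c(hits, s)
  }
  hits
}

# -- brute-force six-frame ORF enumeration ---------------------------------
# O(n^2): for every frame and strand, every candidate span is checked codon
# by codon. Mirrors the reporting contract: one ORF per stop-bounded
# segment (earliest start), edge-running segments as partials.
brute_orfs <- function(seq, min_aa = 5, starts = "ATG") {
  code <- Biostrings::getGeneticCode("11")
  stops <- names(code)[code == "*"]
  L <- nchar(seq)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc
    for (f in 0:2) {
      ncod <- (nchar(s) - f) %/% 3
      if (ncod < 1) next
      cods <- substring(s, f + 1 + 3 * (0:(ncod - 1)), f + 3 * (1:ncod))
      stop_pos <- which(cods %in% stops)
      bounds <- c(0, stop_pos, if (!length(stop_pos) || max(stop_pos) < ncod)
        ncod + 1L else NULL)
      segs <- cbind(head(bounds, -1) + 1, tail(bounds, -1) - 1)
      for (r in seq_len(nrow(segs))) {
        b <- segs[r, 1]; e <- segs[r, 2]
        if (e < b) next
        has_stop <- (e + 1) <= ncod && (e + 1) %in% stop_pos
        st_idx <- b - 1 + which(cods[b:e] %in% starts)
        if (length(st_idx)) {
          from <- st_idx[1]
          if (e - from + 1 >= min_aa)
            out[[length(out) + 1]] <- list(from = from,
                                           to = if (has_stop) e + 1 else e,
                                           f = f, strand = strand,
                                           has_start = TRUE,
                                           has_stop = has_stop)
        } else if (b == 1 && (e - b + 1) >= min_aa) {
          out[[length(out) + 1]] <- list(from = b,
                                         to = if (has_stop) e + 1 else e,
                                         f = f, strand = strand,
                                         has_start = FALSE,
                                         has_stop = has_stop)
        }
      }
    }
  }
  do.call(rbind, lapply(out, function(o) {
    nt_from <- o$f + (o$from - 1) * 3 + 1
    nt_to <- o$f + o$to * 3
    co <- if (o$strand == "+") c(nt_from, nt_to) else
      c(L - nt_to + 1, L - nt_from + 1)
    data.frame(start = co[1], end = co[2], strand = o$strand,
               has_start = o$has_start, has_stop = o$has_stop)
  }))
}

# deterministic random gene: start codon + n sense codons + stop
random_gene <- function(n_codons) {
  code <- Biostrings::getGeneticCode("11")
  sense <- names(code)[code != "*"]
  paste(c("ATG", sample(sense, n_codons, replace = TRUE), "TAA"),
        collapse = "")
}
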