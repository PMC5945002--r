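# Six-frame ORF prediction and translation on assembled contigs.

#' Translate a codon-multiple nucleotide sequence
#'
#' Standard bacterial translation (genetic code table 11 shares its
#' codon-to-residue map with the standard code): the trailing stop codon, if
#' present, is dropped; internal stops are preserved as `*` so callers can
#' flag them; codons containing `N` translate to `X`. A leading alternative
#' start codon (`GTG`/`TTG`) is rendered `M` when `initiator = TRUE`.
#'
#' @param ntSeq A nucleotide string (character scalar or `DNAString`),
#'   length divisible by 3.
#' @param table Genetic code id passed to [Biostrings::getGeneticCode()].
#' @param initiator Render a leading non-ATG start codon as `M`.
#' @return A character scalar of amino-acid residues.
#' @export
#' @examples
#' translateCds("ATGTAA")  # "M"
translateCds <- function(ntSeq, table = "11", initiator = TRUE) {
  s <- toupper(as.character(ntSeq))
  n <- nchar(s)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  if (n == 0L) return("")
  code <- Biostrings::getGeneticCode(table)
  codons <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"  # ambiguity (N) never resolves
  if (initiator && aa[1L] != "X" && codons[1L] %in% c("ATG", "GTG", "TTG"))
    aa[1L] <- "M"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  paste(aa, collapse = "")
}

# per-frame codon translation used by the scanner: returns the residue vector
# including '*' stops, NA-free
.frame_codons <- function(s, offset) {
  n <- nchar(s)
  ncod <- (n - offset) %/% 3L
  if (ncod < 1L) return(character(0))
  st <- offset + seq(1L, by = 3L, length.out = ncod)
  substring(s, st, st + 2L)
}

#' Predict open reading frames in all six frames
#'
#' Every stop-bounded segment of each reading frame is examined. A segment
#' with an in-frame start codon and terminal stop becomes a complete ORF
#' (earliest start wins, so one ORF per segment). Segments running off a
#' contig edge are reported as partial ORFs with the corresponding
#' `has_start`/`has_stop` flag `FALSE`, so that the completeness filter, not
#' the gene finder, decides the complete/partial split. Codons containing
#' `N` translate to `X` and never act as start or stop.
#'
#' @param contigs A [Biostrings::DNAStringSet] (or single `DNAString`).
#' @param minAa Minimum protein length in residues (stop excluded);
#'   default 100 removes spurious micro-ORFs while passing every known
#'   flavin-dependent halogenase (~460-540 aa).
#' @param startCodons Character vector of permitted start codons.
#' @param table Genetic code id (see [translateCds()]).
#' @return A [GenomicRanges::GRanges] on the forward strand coordinates of
#'   each contig (1-based inclusive; a complete ORF spans start codon through
#'   stop codon), with metadata columns `orf_id`, `frame` (0-2 on the
#'   reading strand), `protein`, `has_start`, `has_stop`.
#' @export
findOrfs <- function(contigs, minAa = 100L, startCodons = "ATG",
                     table = "11") {
  if (is(contigs, "DNAString")) {
    contigs <- Biostrings::DNAStringSet(contigs)
    if (is.null(names(contigs))) names(contigs) <- "contig"
  }
  stopifnot(is(contigs, "DNAStringSet"))
  if (minAa < 1L) stop("minAa must be >= 1")
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must carry unique names")
  code <- Biostrings::getGeneticCode(table)
  stops <- names(code)[code == "*"]
  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    cid <- names(contigs)[ci]
    fwd <- toupper(as.character(contigs[[ci]]))
    L <- nchar(fwd)
    rev <- as.character(Biostrings::reverseComplement(contigs[[ci]]))
    rows <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else rev
      for (f in 0:2) {
        codons <- .frame_codons(s, f)
        ncod <- length(codons)
        if (ncod < 2L) next
        is_stop <- codons %in% stops
        is_start <- codons %in% startCodons
        stop_idx <- which(is_stop)
        # segment boundaries in codon indices: (prev_stop, next_stop]
        seg_begin <- c(1L, stop_idx + 1L)
        seg_stop <- c(stop_idx, NA_integer_)  # NA = runs off the edge
        for (si in seq_along(seg_begin)) {
          b <- seg_begin[si]; e_stop <- seg_stop[si]
          seg_end <- if (is.na(e_stop)) ncod else e_stop - 1L  # last sense codon
          if (seg_end < b) next
          starts_here <- which(is_start[b:seg_end])
          edge5 <- b == 1L                  # no upstream stop: 5' edge
          edge3 <- is.na(e_stop)            # no downstream stop: 3' edge
          if (length(starts_here)) {
            first_start <- b + starts_here[1L] - 1L
            aa_len <- seg_end - first_start + 1L
            if (aa_len >= minAa) {
              rows[[length(rows) + 1L]] <- list(
                cod_from = first_start,
                cod_to = if (edge3) seg_end else e_stop,
                strand = strand, frame = f,
                has_start = TRUE, has_stop = !edge3,
                prot = paste(ifelse(is.na(code[codons[first_start:seg_end]]),
                                    "X", code[codons[first_start:seg_end]]),
                             collapse = ""))
              rows[[length(rows)]]$prot <- sub("^.",
                "M", rows[[length(rows)]]$prot)
            }
          } else if (edge5) {
            aa_len <- seg_end - b + 1L
            if (aa_len >= minAa) {
              rows[[length(rows) + 1L]] <- list(
                cod_from = b,
                cod_to = if (edge3) seg_end else e_stop,
                strand = strand, frame = f,
                has_start = FALSE, has_stop = !edge3,
                prot = paste(ifelse(is.na(code[codons[b:seg_end]]),
                                    "X", code[codons[b:seg_end]]),
                             collapse = ""))
            }
          }
        }
      }
    }
    if (!length(rows)) { out[[ci]] <- NULL; next }
    df <- do.call(rbind, lapply(rows, function(r) {
      # codon index -> nt coords on the reading strand
      nt_from <- r$frame + (r$cod_from - 1L) * 3L + 1L
      nt_to <- r$frame + r$cod_to * 3L
      if (r$strand == "+") {
        st <- nt_from; en <- nt_to
      } else {
        st <- L - nt_to + 1L; en <- L - nt_from + 1L
      }
      data.frame(contig = cid, start = st, end = en, strand = r$strand,
                 frame = r$frame, protein = r$prot,
                 has_start = r$has_start, has_stop = r$has_stop,
                 stringsAsFactors = FALSE)
    }))
    out[[ci]] <- df
  }
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = out$contig,
    ranges = IRanges::IRanges(start = out$start, end = out$end),
    strand = out$strand)
  S4Vectors::mcols(gr)$orf_id <- sprintf("%s_orf%03d", out$contig,
                                         stats::ave(seq_len(nrow(out)),
                                                    out$contig,
                                                    FUN = seq_along))
  S4Vectors::mcols(gr)$frame <- out$frame
  S4Vectors::mcols(gr)$protein <- out$protein
  S4Vectors::mcols(gr)$has_start <- out$has_start
  S4Vectors::mcols(gr)$has_stop <- out$has_stop
  gr
}
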