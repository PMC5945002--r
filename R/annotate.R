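# Conserved-motif scanning, catalytic-residue mapping and the completeness
# filter that splits predicted genes into complete and partial candidates.

#' Default conserved-motif definitions
#'
#' The two sequence fingerprints used to recognise flavin-dependent
#' halogenases: the Rossmann-like FAD-binding module `GxGxxG` near the
#' N-terminus, and the `WxWxIP` motif thought to block monooxygenase
#' activity. In a degenerate pattern a letter matches itself and `x` matches
#' any residue.
#'
#' @return A data.frame with columns `name` and `pattern`.
#' @export
#' @examples
#' defaultMotifs()
defaultMotifs <- function() {
  data.frame(name = c("GxGxxG", "WxWxIP"),
             pattern = c("GxGxxG", "WxWxIP"),
             stringsAsFactors = FALSE)
}

#' Synthetic BrvH-like stand-in protein
#'
#' A 509-residue synthetic protein (1530 bp CDS equivalent) constructed to
#' carry the published anchor layout of the BrvH halogenase: first GxGxxG
#' match at residues 16-21, catalytic lysine at 83, first WxWxIP match at
#' 275-280, catalytic glutamate at 349. It is a generated stand-in for
#' exercising motif scanning and residue mapping at realistic coordinates,
#' not the real BrvH sequence.
#'
#' @return A length-1 [Biostrings::AAStringSet].
#' @export
#' @examples
#' scanMotifs(as.character(brvhStandin()))[1:2, ]
brvhStandin <- function() {
  readFasta(system.file("extdata", "brvh_synthetic_standin.fasta",
                        package = "fhalminer"), "protein")
}

.motif_regex <- function(pattern) {
  if (nchar(pattern) < 2L || grepl("[^A-Zx]", pattern))
    stop("invalid motif pattern: ", pattern)
  gsub("x", ".", pattern, fixed = TRUE)
}

#' Scan a protein for degenerate motifs
#'
#' Reports every (possibly overlapping) occurrence of each motif, ascending
#' by start position.
#'
#' @param protein A protein sequence (character scalar or `AAString`).
#' @param motifs A data.frame with `name` and `pattern` columns; defaults to
#'   [defaultMotifs()].
#' @return A data.frame with columns `motif`, `start`, `end` (1-based
#'   inclusive) and `matched`; zero rows when nothing matches.
#' @export
#' @examples
#' scanMotifs("AAGAGAAGAA")  # GxGxxG at 3
scanMotifs <- function(protein, motifs = defaultMotifs()) {
  s <- toupper(as.character(protein))
  out <- lapply(seq_len(nrow(motifs)), function(i) {
    rx <- .motif_regex(motifs$pattern[i])
    w <- nchar(motifs$pattern[i])
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1L]]
    if (m[1L] == -1L) return(NULL)
    starts <- as.integer(m)
    data.frame(motif = motifs$name[i], start = starts,
               end = starts + w - 1L,
               matched = substring(s, starts, starts + w - 1L),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), matched = character(0),
                      stringsAsFactors = FALSE))
  out[order(match(out$motif, motifs$name), out$start), , drop = FALSE]
}

#' Map catalytic residues onto a candidate through the profile HMM
#'
#' Each anchor names a training-alignment row of the model, a 1-based
#' position in that reference, and the expected residue (for instance the
#' catalytic lysine at position 83). The anchor's match column is located
#' through the reference's stored residue-to-column map and projected onto
#' the query through its Viterbi residue-to-column map. A column deleted in
#' the query yields `NA` position and `match = FALSE`.
#'
#' @param protein Candidate protein sequence.
#' @param hmm A [ProfileHMM-class] whose `refMap` contains the anchors'
#'   reference rows.
#' @param anchors A data.frame with columns `ref`, `position`, `residue`.
#' @return A data.frame with columns `ref`, `anchor_position`,
#'   `mapped_position`, `observed`, `match`.
#' @export
mapCatalyticResidues <- function(protein, hmm, anchors) {
  s <- toupper(as.character(protein))
  vit <- viterbiAlign(hmm, s)
  res <- lapply(seq_len(nrow(anchors)), function(i) {
    ref <- anchors$ref[i]
    pos <- anchors$position[i]
    if (is.null(hmm@refMap[[ref]]))
      stop("reference ", ref, " is not a training row of the model")
    rmap <- hmm@refMap[[ref]]
    if (pos < 1L || pos > length(rmap))
      stop("anchor position ", pos, " outside reference ", ref)
    col <- rmap[pos]
    if (col == 0L)
      stop("anchor position ", pos, " of ", ref,
           " falls in an insert column and cannot anchor")
    qpos <- which(vit$map == col)
    if (length(qpos) != 1L) {
      data.frame(ref = ref, anchor_position = pos,
                 mapped_position = NA_integer_, observed = NA_character_,
                 match = FALSE, stringsAsFactors = FALSE)
    } else {
      obs <- substr(s, qpos, qpos)
      data.frame(ref = ref, anchor_position = pos, mapped_position = qpos,
                 observed = obs, match = identical(obs, anchors$residue[i]),
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, res)
}

#' Completeness filter configuration
#'
#' Encodes the completeness rule applied to predicted genes: a start and a
#' stop codon must be present, the required conserved motifs must each match
#' at least once, the protein length must fit the size range of known
#' halogenases, and the model E-value must pass. The default length window
#' of 460-600 residues admits both variant A halogenases (which cluster
#' near 510-540 aa) and the roughly 70-residue-shorter variant B proteins.
#'
#' @param requireStart,requireStop Logical; default `TRUE`.
#' @param requiredMotifs Character vector of motif names; default
#'   `c("GxGxxG", "WxWxIP")`.
#' @param lenMin,lenMax Protein length bounds in residues.
#' @param evalueMax Maximum E-value.
#' @return A list of class `completenessConfig`.
#' @export
completenessConfig <- function(requireStart = TRUE, requireStop = TRUE,
                               requiredMotifs = c("GxGxxG", "WxWxIP"),
                               lenMin = 460L, lenMax = 600L,
                               evalueMax = 1e-6) {
  if (lenMin >= lenMax) stop("lenMin must be < lenMax")
  if (evalueMax <= 0) stop("evalueMax must be positive")
  structure(list(requireStart = requireStart, requireStop = requireStop,
                 requiredMotifs = requiredMotifs,
                 lenMin = lenMin, lenMax = lenMax, evalueMax = evalueMax),
            class = "completenessConfig")
}

#' Assess the completeness of a predicted gene
#'
#' Conjunction of four criteria: start/stop codons present, required motifs
#' present, protein length within the configured window, and E-value at or
#' below the threshold. Every failed criterion carries a human-readable
#' reason.
#'
#' @param hasStart,hasStop Logical flags from the ORF finder.
#' @param proteinLength Protein length in residues.
#' @param motifHits Data frame from [scanMotifs()].
#' @param evalue E-value of the gene's HMM hit.
#' @param cfg A [completenessConfig()].
#' @return A list with per-criterion logicals (`start_stop`, `motifs`,
#'   `length`, `evalue`), `complete` (their conjunction) and `reasons`
#'   (character vector, empty when complete).
#' @export
assessCompleteness <- function(hasStart, hasStop, proteinLength, motifHits,
                               evalue, cfg = completenessConfig()) {
  reasons <- character(0)
  ok_ss <- (!cfg$requireStart || isTRUE(hasStart)) &&
           (!cfg$requireStop || isTRUE(hasStop))
  if (!ok_ss)
    reasons <- c(reasons, sprintf("start_stop: has_start=%s has_stop=%s",
                                  hasStart, hasStop))
  present <- unique(motifHits$motif)
  missing <- setdiff(cfg$requiredMotifs, present)
  ok_mot <- length(missing) == 0L
  if (!ok_mot)
    reasons <- c(reasons, paste0("motifs: missing ",
                                 paste(missing, collapse = ", ")))
  ok_len <- proteinLength >= cfg$lenMin && proteinLength <= cfg$lenMax
  if (!ok_len)
    reasons <- c(reasons, sprintf("length: %d outside [%d, %d]",
                                  proteinLength, cfg$lenMin, cfg$lenMax))
  ok_ev <- is.finite(evalue) && evalue <= cfg$evalueMax
  if (!ok_ev)
    reasons <- c(reasons, sprintf("evalue: %.3g > %.3g", evalue,
                                  cfg$evalueMax))
  list(start_stop = ok_ss, motifs = ok_mot, length = ok_len,
       evalue = ok_ev, complete = ok_ss && ok_mot && ok_len && ok_ev,
       reasons = reasons)
}
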