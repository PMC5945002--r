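# End-to-end mining: ORF prediction -> HMM scoring -> E-value filter ->
# completeness -> phylogenetic variant classification, with per-stage
# attrition accounting and artifact writing.

#' Align sequences to a profile HMM's match columns
#'
#' Viterbi-aligns each sequence and places its matched residues into the
#' model's match columns (insertions are dropped, deletions become gaps),
#' yielding a consistent fixed-width alignment suitable for distance
#' phylogenetics across candidates and references.
#'
#' @param hmm A [ProfileHMM-class].
#' @param seqs Named character vector or [Biostrings::AAStringSet].
#' @return An equal-width gapped [Biostrings::AAStringSet] with `L` columns.
#' @export
hmmAlign <- function(hmm, seqs) {
  ch <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(ch)) || anyDuplicated(names(ch)))
    stop("sequences must carry unique names")
  L <- hmm@L
  rows <- vapply(ch, function(s) {
    v <- viterbiAlign(hmm, s)
    row <- rep("-", L)
    matched <- v$map > 0L
    row[v$map[matched]] <- strsplit(s, "", fixed = TRUE)[[1L]][matched]
    paste(row, collapse = "")
  }, character(1))
  out <- Biostrings::AAStringSet(rows)
  names(out) <- names(ch)
  out
}

#' Mining pipeline configuration
#'
#' The operational E-value cutoff is derived at run time from the model's
#' Gumbel calibration as `decoyFpr * dbSize` (expected decoy false positives
#' per screen), because E-value thresholds quoted against HMMER3 — such as
#' the 1e-150 cutoff used in the original marine metagenome screen, kept
#' here as `paperEvalueCutoff` for provenance — are not numerically
#' transferable to a different scorer. Set `evalueMax` to override the
#' derived cutoff explicitly.
#'
#' @param minAa,startCodons,geneticCode ORF-finder options (see
#'   [findOrfs()]).
#' @param evalueMax Explicit E-value cutoff, or `NULL` to derive one.
#' @param decoyFpr Per-sequence decoy false-positive rate used to derive the
#'   cutoff when `evalueMax` is `NULL`.
#' @param paperEvalueCutoff The literal HMMER3-scale cutoff quoted in published FHal
#'   screens, recorded in the run summary for provenance only.
#' @param completeness A [completenessConfig()].
#' @param bootstrapReps Bootstrap replicates for the classification tree
#'   (default 1000).
#' @param classify Run the phylogenetic classification stage.
#' @param seed Integer seed for calibration/bootstrap.
#' @return A list of class `miningConfig`.
#' @export
miningConfig <- function(minAa = 100L, startCodons = "ATG",
                         geneticCode = "11", evalueMax = NULL,
                         decoyFpr = 1e-6, paperEvalueCutoff = 1e-150,
                         completeness = completenessConfig(),
                         bootstrapReps = 1000L, classify = TRUE,
                         seed = defaultSeed()) {
  stopifnot(minAa >= 1L, decoyFpr > 0, bootstrapReps >= 1L)
  structure(list(minAa = as.integer(minAa), startCodons = startCodons,
                 geneticCode = geneticCode, evalueMax = evalueMax,
                 decoyFpr = decoyFpr, paperEvalueCutoff = paperEvalueCutoff,
                 completeness = completeness,
                 bootstrapReps = as.integer(bootstrapReps),
                 classify = classify, seed = as.integer(seed)),
            class = "miningConfig")
}

#' Run the halogenase mining pipeline on assembled contigs
#'
#' Stages, in order: six-frame ORF prediction; Forward scoring of every
#' predicted protein against the model; overlap resolution (the best-scoring
#' ORF wins among overlapping predictions, since the unit of interest is the
#' gene, not the domain hit); E-value filtering; motif and completeness
#' assessment; and, when references are supplied, NJ/bootstrap variant
#' classification of the complete candidates. Every stage's survivor count
#' enters the attrition table, which is checked to be non-increasing.
#'
#' @param contigs A [Biostrings::DNAStringSet] of assembled contigs.
#' @param hmm A calibrated [ProfileHMM-class] (an uncalibrated model is
#'   calibrated on the fly with default decoy settings).
#' @param config A [miningConfig()].
#' @param refsA,refsB Optional named reference protein sets (character or
#'   `AAStringSet`), at least 2 per class, for variant classification.
#' @param outDir Optional directory: writes `orfs.gff3`, `candidates.tsv`,
#'   `classification.nwk` (when classification runs) and `summary.json`.
#' @return A list of class `fhalReport`: `candidates` (per-ORF data.frame
#'   with scores, E-values, motif spans, completeness verdicts and reasons,
#'   variant calls), `attrition`, `tree` (or `NULL`), `orfs` (`GRanges`),
#'   `thresholds`.
#' @export
runMining <- function(contigs, hmm, config = miningConfig(),
                      refsA = NULL, refsB = NULL, outDir = NULL) {
  stopifnot(is(hmm, "ProfileHMM"), inherits(config, "miningConfig"))
  if (is.null(calibration(hmm))) {
    message("model is uncalibrated: calibrating with default decoy settings")
    hmm <- calibrateHmm(hmm, seed = config$seed)
  }
  orfs <- findOrfs(contigs, minAa = config$minAa,
                   startCodons = config$startCodons,
                   table = config$geneticCode)
  n_predicted <- length(orfs)
  if (n_predicted == 0L) {
    warning("no ORFs found: returning an empty report")
    att <- data.frame(stage = c("predicted", "scored", "evalue_pass",
                                "complete", "classified"),
                      n = c(0L, 0L, 0L, 0L, 0L))
    return(structure(list(candidates = data.frame(), attrition = att,
                          tree = NULL, orfs = orfs,
                          thresholds = list()), class = "fhalReport"))
  }
  mc <- S4Vectors::mcols(orfs)
  prot <- mc$protein
  bits <- vapply(prot, function(p) forwardBits(hmm, p), numeric(1),
                 USE.NAMES = FALSE)
  dbSize <- length(prot)
  fit <- calibration(hmm)
  ev <- evalueFromFit(fit, bits, dbSize)
  evalueMax <- config$evalueMax
  if (is.null(evalueMax)) evalueMax <- config$decoyFpr * dbSize
  cand <- data.frame(
    orf_id = mc$orf_id,
    contig = as.character(GenomicRanges::seqnames(orfs)),
    start = GenomicRanges::start(orfs), end = GenomicRanges::end(orfs),
    strand = as.character(GenomicRanges::strand(orfs)),
    frame = mc$frame, has_start = mc$has_start, has_stop = mc$has_stop,
    protein_length = nchar(prot), bits = bits, evalue = ev,
    stringsAsFactors = FALSE)
  # overlap resolution: among overlapping ORFs (any frame or strand), the
  # best-scoring one represents the locus
  ov <- GenomicRanges::findOverlaps(orfs, ignore.strand = TRUE)
  keep <- rep(TRUE, n_predicted)
  for (h in seq_along(ov)) {
    i <- S4Vectors::queryHits(ov)[h]; j <- S4Vectors::subjectHits(ov)[h]
    if (i >= j) next
    loser <- if (bits[i] >= bits[j]) j else i
    keep[loser] <- FALSE
  }
  cand$best_in_locus <- keep
  cand$evalue_pass <- keep & (ev <= evalueMax)
  # motif scan + completeness on E-value survivors
  cand$gxgxxg_first <- NA_integer_
  cand$wxwxip_first <- NA_integer_
  cand$complete <- FALSE
  cand$reasons <- ""
  ccfg <- config$completeness
  for (i in which(cand$evalue_pass)) {
    hits <- scanMotifs(prot[i])
    g1 <- hits$start[hits$motif == "GxGxxG"]
    w1 <- hits$start[hits$motif == "WxWxIP"]
    cand$gxgxxg_first[i] <- if (length(g1)) g1[1L] else NA_integer_
    cand$wxwxip_first[i] <- if (length(w1)) w1[1L] else NA_integer_
    cc <- assessCompleteness(cand$has_start[i], cand$has_stop[i],
                             cand$protein_length[i], hits, ev[i], ccfg)
    cand$complete[i] <- cc$complete
    cand$reasons[i] <- paste(cc$reasons, collapse = "; ")
  }
  # phylogenetic classification of complete candidates
  tree <- NULL
  cand$variant <- NA_character_
  cand$variant_evidence <- NA_character_
  complete_idx <- which(cand$complete)
  n_classified <- 0L
  can_classify <- config$classify && !is.null(refsA) && !is.null(refsB) &&
    length(refsA) >= 2L && length(refsB) >= 2L && length(complete_idx) > 0L
  if (can_classify) {
    qnames <- cand$orf_id[complete_idx]
    seqs <- c(setNames(prot[complete_idx], qnames),
              setNames(as.character(refsA), names(refsA)),
              setNames(as.character(refsB), names(refsB)))
    msa <- hmmAlign(hmm, seqs)
    tree <- bootstrapSupport(msa, nReps = config$bootstrapReps,
                             seed = config$seed)
    refLengths <- c(nchar(as.character(refsA)), nchar(as.character(refsB)))
    names(refLengths) <- c(names(refsA), names(refsB))
    for (i in complete_idx) {
      call <- classifyVariant(tree, names(refsA), names(refsB),
                              cand$orf_id[i],
                              queryLength = cand$protein_length[i],
                              refLengths = refLengths)
      cand$variant[i] <- call$call
      cand$variant_evidence[i] <- call$evidence
    }
    n_classified <- sum(cand$variant[complete_idx] %in% c("A", "B"))
  }
  attrition <- data.frame(
    stage = c("predicted", "scored", "evalue_pass", "complete", "classified"),
    n = c(n_predicted, n_predicted, sum(cand$evalue_pass),
          sum(cand$complete),
          if (can_classify) n_classified else sum(cand$complete)))
  if (any(diff(attrition$n) > 0L))
    stop("attrition table is not monotone: internal error")
  thresholds <- list(evalue_max = evalueMax, decoy_fpr = config$decoyFpr,
                     db_size = dbSize,
                     paper_evalue_cutoff = config$paperEvalueCutoff,
                     min_aa = config$minAa,
                     length_window = c(ccfg$lenMin, ccfg$lenMax),
                     required_motifs = ccfg$requiredMotifs,
                     bootstrap_reps = config$bootstrapReps,
                     seed = config$seed,
                     calibration = list(mu = fit@mu, lambda = fit@lambda,
                                        n_decoys = fit@nDecoys))
  report <- structure(list(candidates = cand, attrition = attrition,
                           tree = tree, orfs = orfs,
                           thresholds = thresholds),
                      class = "fhalReport")
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeGff3(orfs, file.path(outDir, "orfs.gff3"))
    utils::write.table(cand, file.path(outDir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tree))
      writeNewickTree(tree, file.path(outDir, "classification.nwk"))
    jsonlite::write_json(list(attrition = attrition,
                              thresholds = thresholds),
                         file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}

#' @export
print.fhalReport <- function(x, ...) {
  cat("Halogenase mining report\n")
  print(x$attrition, row.names = FALSE)
  if (!is.null(x$tree))
    cat("classification tree over", length(x$tree$tip.label), "taxa\n")
  invisible(x)
}

#' Two-step profile HMM construction from seed references
#'
#' Expands a set of characterised reference proteins by collecting close
#' homologs from a database (50% identity / 90% reference coverage by
#' default), aligns the retained set with the progressive aligner, builds
#' the profile HMM and calibrates its E-values.
#'
#' @param refs Non-empty named reference proteins
#'   ([Biostrings::AAStringSet]).
#' @param database Candidate proteins to screen for homologs (may be empty:
#'   the model is then built from the references alone).
#' @param idThreshold,covThreshold Homolog-collection thresholds.
#' @param occupancyThreshold,pseudocountWeight See [buildHmm()].
#' @param calibrate Calibrate E-values after building.
#' @param nDecoys,decoyLength,seed Calibration settings.
#' @return A list: `hmm` (a calibrated [ProfileHMM-class]), `msa` (the
#'   training alignment), `retained` (ids that entered the alignment).
#' @export
runHmmConstruction <- function(refs, database = NULL, idThreshold = 0.50,
                               covThreshold = 0.90,
                               occupancyThreshold = 0.5,
                               pseudocountWeight = 1, calibrate = TRUE,
                               nDecoys = 200L, decoyLength = 400L,
                               seed = defaultSeed()) {
  if (length(refs) == 0L) stop("refs must be non-empty")
  extra <- if (is.null(database) || length(database) == 0L)
    Biostrings::AAStringSet() else
    collectHomologs(refs, database, idThreshold, covThreshold)
  extra <- extra[setdiff(names(extra), names(refs))]
  training <- c(Biostrings::AAStringSet(as.character(refs)), extra)
  names(training) <- c(names(refs), names(extra))
  if (length(training) < 2L)
    stop("fewer than 2 sequences retained: cannot build a model")
  msa <- progressiveMsa(training)
  hmm <- buildHmm(msa, occupancyThreshold, pseudocountWeight,
                  name = "mined-fhal")
  if (calibrate)
    hmm <- calibrateHmm(hmm, nDecoys = nDecoys, decoyLength = decoyLength,
                        seed = seed)
  list(hmm = hmm, msa = msa, retained = names(training))
}
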