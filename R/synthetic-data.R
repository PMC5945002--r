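# Synthetic benchmark metagenomes with planted halogenase-like genes,
# decoys and a truth manifest. The generator emulates the cohort structure
# the mining analysis assumes (complete and edge-truncated genes of two
# homologous variants differing by ~70 residues, plus decoys that separate
# the E-value filter from the motif filter); it does not emulate real
# taxonomic composition, codon usage or assembly artefacts.

.synthetic_hmm <- function(consensus, motif_cols, name,
                           conc_plain = 0.75, conc_motif = 0.998,
                           p_mi = 0.002, p_md = 0.002) {
  L <- length(consensus)
  conc <- rep(conc_plain, L)
  conc[motif_cols] <- conc_motif
  em <- matrix(0, L, 20L, dimnames = list(NULL, AA20))
  for (k in seq_len(L)) {
    v <- ROBINSON_FREQS * (1 - conc[k])
    v[consensus[k]] <- v[consensus[k]] + conc[k]
    em[k, ] <- v / sum(v)
  }
  trans <- matrix(0, L + 1L, 7L, dimnames = list(0:L, TRANS_COLS))
  trans[1L, "mm"] <- 1 - p_md; trans[1L, "md"] <- p_md
  trans[1L, c("im", "dm")] <- 1
  if (L > 1L) for (k in 2:L) {
    trans[k, c("mm", "mi", "md")] <- c(1 - p_mi - p_md, p_mi, p_md)
    trans[k, c("im", "ii")] <- c(0.9, 0.1)
    trans[k, c("dm", "dd")] <- c(0.9, 0.1)
  }
  trans[L + 1L, ] <- c(1, 0, 0, 1, 0, 1, 0)
  new("ProfileHMM", L = as.integer(L), matchEmit = em,
      insertEmit = ROBINSON_FREQS, trans = trans,
      background = ROBINSON_FREQS, calibration = NULL,
      refMap = list(), name = name)
}

# motif layout of the variant-A family model (1-based match columns),
# echoing the anchor coordinates of known FHals: FAD-binding GxGxxG at
# 16-21, catalytic K at 83, WxWxIP at 275-280, catalytic E at 349
.A_FIXED <- c(`1` = "M", `16` = "G", `18` = "G", `21` = "G", `83` = "K",
              `275` = "W", `277` = "W", `279` = "I", `280` = "P",
              `349` = "E")

#' Construct the synthetic reference family models
#'
#' Builds two related profile HMMs standing in for characterised FHal
#' families: a variant-A model of 535 match states carrying the canonical
#' motif layout (GxGxxG at columns 16-21, catalytic lysine at 83, WxWxIP at
#' 275-280, catalytic glutamate at 349), and a variant-B model exactly 70
#' match states shorter, derived from A by deleting a C-terminal block
#' (columns 351-420) and re-drawing a quarter of the remaining non-motif
#' consensus columns, so the two families are homologous but distinct.
#' Motif columns have near-deterministic emissions (entropy far below
#' non-motif columns); non-motif columns put 75% mass on their consensus.
#' Eight gap-free seed sequences per family are sampled from the match
#' emissions as seed alignments.
#'
#' @param seed Integer seed.
#' @return A list: `hmmA`, `hmmB` ([ProfileHMM-class]), `seedA`, `seedB`
#'   (gap-free [Biostrings::AAStringSet] seed alignments), `anchorsA`
#'   (data.frame of catalytic anchor positions in the A consensus).
#' @export
makeReferenceModels <- function(seed = defaultSeed()) {
  .with_seed(seed, {
    LA <- 535L
    consA <- sample(AA20, LA, replace = TRUE, prob = ROBINSON_FREQS)
    fixed <- .A_FIXED
    consA[as.integer(names(fixed))] <- fixed
    motifA <- as.integer(names(fixed))
    hmmA <- .synthetic_hmm(consA, motifA, "synthA")
    # variant B: remove a 70-column block downstream of the anchors, then
    # re-draw 25% of the remaining plain columns
    drop <- 351:420
    consB <- consA[-drop]
    motifB <- motifA  # all anchor columns precede the dropped block
    plain <- setdiff(seq_along(consB), motifB)
    redraw <- sort(sample(plain, round(0.25 * length(plain))))
    consB[redraw] <- sample(AA20, length(redraw), replace = TRUE,
                            prob = ROBINSON_FREQS)
    hmmB <- .synthetic_hmm(consB, motifB, "synthB")
    sample_rows <- function(hmm, prefix, n = 8L) {
      em <- hmm@matchEmit
      rows <- vapply(seq_len(n), function(i)
        paste(AA20[apply(em, 1L, function(p) sample.int(20L, 1L, prob = p))],
              collapse = ""), character(1))
      out <- Biostrings::AAStringSet(rows)
      names(out) <- sprintf("%s_%d", prefix, seq_len(n))
      out
    }
    seedA <- sample_rows(hmmA, "refA")
    seedB <- sample_rows(hmmB, "refB")
    anchorsA <- data.frame(
      name = c("FAD_GxGxxG", "catalytic_K", "WxWxIP", "catalytic_E"),
      position = c(16L, 83L, 275L, 349L),
      residue = c("G", "K", "W", "E"), stringsAsFactors = FALSE)
    list(hmmA = hmmA, hmmB = hmmB, seedA = seedA, seedB = seedB,
         anchorsA = anchorsA)
  })
}

# uniform synonymous reverse translation (no codon-usage model: codon bias
# is irrelevant to every downstream computation tested)
.codon_table <- function() {
  if (is.null(.pkg_cache$codons)) {
    code <- Biostrings::getGeneticCode("11")
    sense <- code[code != "*"]
    .pkg_cache$codons <- split(names(sense), unname(sense))
  }
  .pkg_cache$codons
}

.reverse_translate <- function(protein) {
  tab <- .codon_table()
  aas <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(aas, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot reverse-translate residue ", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  if (aas[1L] == "M") codons[1L] <- "ATG" else codons <- c("ATG", codons)
  paste(c(codons, "TAA"), collapse = "")
}

.random_dna <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Benchmark configuration
#'
#' Defaults echo the cohort shape of the original marine screen purely as a
#' familiar default (42 complete variant-A genes and 254 planted elements in
#' total); this is a configurable simulation, not a reproduction of the
#' published counts.
#'
#' @param nCompleteA,nCompleteB Complete genes planted per variant.
#' @param nPartial Edge-truncated partial genes (classes alternate A/B).
#' @param nDecoys Decoys: half shuffled planted proteins, half
#'   "monooxygenase-like" sequences retaining GxGxxG with WxWxIP ablated.
#' @param contigLength Length-2 vector, min/max contig length (nt).
#' @param truncationFraction Fraction of a partial gene removed at a contig
#'   edge, in (0, 1).
#' @param gc G+C fraction of background sequence.
#' @param nBackgroundContigs Gene-free background contigs appended.
#' @param seed Integer seed.
#' @return A list of class `benchmarkConfig`.
#' @export
benchmarkConfig <- function(nCompleteA = 42L, nCompleteB = 35L,
                            nPartial = 77L, nDecoys = 100L,
                            contigLength = c(2500L, 6000L),
                            truncationFraction = 0.35, gc = 0.45,
                            nBackgroundContigs = 20L,
                            seed = defaultSeed()) {
  stopifnot(nCompleteA >= 0, nCompleteB >= 0, nPartial >= 0, nDecoys >= 0,
            truncationFraction > 0, truncationFraction < 1,
            gc > 0, gc < 1, length(contigLength) == 2L)
  if (contigLength[1L] < 3L * 600L)
    stop("contigs must be at least 3x the minimum gene length")
  structure(list(nCompleteA = nCompleteA, nCompleteB = nCompleteB,
                 nPartial = nPartial, nDecoys = nDecoys,
                 contigLength = as.integer(contigLength),
                 truncationFraction = truncationFraction, gc = gc,
                 nBackgroundContigs = nBackgroundContigs,
                 seed = as.integer(seed)),
            class = "benchmarkConfig")
}

.ablate_wxwxip <- function(protein) {
  repeat {
    hits <- scanMotifs(protein, defaultMotifs()[2L, , drop = FALSE])
    if (nrow(hits) == 0L) return(protein)
    substr(protein, hits$start[1L], hits$start[1L]) <- "F"
  }
}

#' Generate a synthetic benchmark metagenome with truth manifest
#'
#' Plants complete, partial and decoy elements on i.i.d. background contigs
#' (one element per contig, so planted elements never overlap), with partial
#' genes truncated by `truncationFraction` at a contig edge so that a start
#' or stop codon is destroyed. Every element is recorded in the manifest.
#' Byte-identical output for a given seed.
#'
#' @param cfg A [benchmarkConfig()].
#' @return A list: `contigs` ([Biostrings::DNAStringSet]), `manifest`
#'   (data.frame: `element_id`, `contig`, `start`, `end`, `strand`, `class`,
#'   `completeness`, `decoy_type`, `protein_length`, `source_model`), and
#'   `models` (the [makeReferenceModels()] output used).
#' @export
makeBenchmark <- function(cfg = benchmarkConfig()) {
  stopifnot(inherits(cfg, "benchmarkConfig"))
  models <- makeReferenceModels(cfg$seed)
  .with_seed(cfg$seed + 1L, {
    specs <- c(
      rep(list(list(class = "A", completeness = "complete", decoy = NA)),
          cfg$nCompleteA),
      rep(list(list(class = "B", completeness = "complete", decoy = NA)),
          cfg$nCompleteB),
      lapply(seq_len(cfg$nPartial), function(i)
        list(class = if (i %% 2L == 1L) "A" else "B",
             completeness = "partial", decoy = NA)),
      lapply(seq_len(cfg$nDecoys), function(i)
        list(class = "decoy", completeness = "complete",
             decoy = if (i %% 2L == 1L) "shuffled" else "monooxygenase")))
    contigs <- character(0)
    rows <- list()
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      model <- if (identical(sp$class, "B")) models$hmmB else models$hmmA
      prot <- .sample_hmm(model)
      dtype <- sp$decoy
      if (identical(dtype, "shuffled"))
        prot <- paste(sample(strsplit(prot, "")[[1L]]), collapse = "")
      if (identical(dtype, "monooxygenase"))
        prot <- .ablate_wxwxip(prot)
      gene <- .reverse_translate(prot)
      glen <- nchar(gene)
      clen <- sample(cfg$contigLength[1L]:cfg$contigLength[2L], 1L)
      if (clen < glen + 100L) clen <- glen + 100L
      strand <- sample(c("+", "-"), 1L)
      cid <- sprintf("contig%04d", i)
      if (sp$completeness == "partial") {
        cut_side <- sample(c("start", "end"), 1L)  # which gene end is lost
        ncut <- round(cfg$truncationFraction * glen)
        frag <- if (cut_side == "start") substr(gene, ncut + 1L, glen)
                else substr(gene, 1L, glen - ncut)
        fl <- nchar(frag)
        ins <- if (strand == "-") Biostrings::reverseComplement(
                 Biostrings::DNAString(frag)) else frag
        ins <- as.character(ins)
        # the missing gene end must fall off the contig edge
        at_left <- (cut_side == "start") == (strand == "+")
        bgseq <- .random_dna(clen - fl, cfg$gc)
        if (at_left) {
          contig <- paste0(ins, bgseq); st <- 1L; en <- fl
        } else {
          contig <- paste0(bgseq, ins); st <- clen - fl + 1L; en <- clen
        }
      } else {
        ins <- if (strand == "-") as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(gene))) else gene
        pos <- sample(51:(clen - glen - 50L), 1L)
        bg <- .random_dna(clen - glen, cfg$gc)
        contig <- paste0(substr(bg, 1L, pos - 1L), ins,
                         substr(bg, pos, clen - glen))
        st <- pos; en <- pos + glen - 1L
      }
      contigs[cid] <- contig
      rows[[i]] <- data.frame(
        element_id = sprintf("elem%04d", i), contig = cid,
        start = st, end = en, strand = strand, class = sp$class,
        completeness = sp$completeness,
        decoy_type = if (is.na(dtype)) NA_character_ else dtype,
        protein_length = nchar(prot),
        source_model = model@name, stringsAsFactors = FALSE)
    }
    for (j in seq_len(cfg$nBackgroundContigs)) {
      cid <- sprintf("bgcontig%04d", j)
      contigs[cid] <- .random_dna(
        sample(cfg$contigLength[1L]:cfg$contigLength[2L], 1L), cfg$gc)
    }
    manifest <- do.call(rbind, rows)
    out <- Biostrings::DNAStringSet(contigs)
    list(contigs = out, manifest = manifest, models = models)
  })
}

#' Write / read a truth manifest as JSON
#'
#' @param manifest The manifest data.frame from [makeBenchmark()].
#' @param path File path.
#' @return `writeManifest` returns `path` invisibly; `readManifest` the
#'   data.frame.
#' @export
writeManifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname writeManifest
#' @export
readManifest <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  as.data.frame(df, stringsAsFactors = FALSE)
}

#' Score pipeline output against a truth manifest
#'
#' A planted gene counts as recovered when a reported candidate on the same
#' contig and strand overlaps at least 80% of its span; for the
#' complete stratum the candidate must additionally carry a complete
#' verdict, since complete genes must survive the completeness filter to
#' appear in the pipeline's final output. Decoy false positives are
#' complete-verdict candidates that do not correspond to any planted
#' (non-decoy) gene.
#'
#' @param report A mining report (see [runMining()]) or its `candidates`
#'   data.frame.
#' @param manifest Truth manifest from the same benchmark.
#' @return A list: `recall` (data.frame per class and completeness stratum),
#'   `precision` (of complete-verdict candidates), and
#'   `decoy_false_positives`.
#' @export
scoreRecovery <- function(report, manifest) {
  cand <- if (is.data.frame(report)) report else report$candidates
  if (nrow(cand) > 0L && nrow(manifest) > 0L &&
      !any(cand$contig %in% manifest$contig))
    stop("mismatched contig ids between report and manifest")
  cand <- cand[cand$evalue_pass, , drop = FALSE]
  planted <- manifest[manifest$class %in% c("A", "B"), , drop = FALSE]
  overlaps <- function(p, need_complete) {
    hits <- cand[cand$contig == p$contig & cand$strand == p$strand, ,
                 drop = FALSE]
    if (need_complete) hits <- hits[hits$complete, , drop = FALSE]
    if (nrow(hits) == 0L) return(FALSE)
    ov <- pmax(0L, pmin(hits$end, p$end) - pmax(hits$start, p$start) + 1L)
    any(ov >= 0.8 * (p$end - p$start + 1L))
  }
  planted$recovered <- vapply(seq_len(nrow(planted)), function(i) {
    p <- planted[i, ]
    overlaps(p, need_complete = p$completeness == "complete")
  }, logical(1))
  recall <- do.call(rbind, lapply(split(planted,
                                        list(planted$class,
                                             planted$completeness),
                                        drop = TRUE), function(g)
    data.frame(class = g$class[1L], completeness = g$completeness[1L],
               n = nrow(g), recovered = sum(g$recovered),
               recall = mean(g$recovered), stringsAsFactors = FALSE)))
  rownames(recall) <- NULL
  complete_cand <- cand[cand$complete, , drop = FALSE]
  pc <- planted[planted$completeness == "complete", , drop = FALSE]
  cand_tp <- vapply(seq_len(nrow(complete_cand)), function(i) {
    h <- complete_cand[i, ]
    any(pc$contig == h$contig & pc$strand == h$strand &
          pmax(0L, pmin(pc$end, h$end) - pmax(pc$start, h$start) + 1L) >=
            0.8 * (pc$end - pc$start + 1L))
  }, logical(1))
  precision <- if (nrow(complete_cand)) mean(cand_tp) else NA_real_
  list(recall = recall, precision = precision,
       decoy_false_positives = if (nrow(complete_cand)) sum(!cand_tp) else 0L)
}
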