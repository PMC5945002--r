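test_that("reference models have the designed lengths and motif layout", {
  mods <- makeReferenceModels(1699)
  expect_equal(hmmLength(mods$hmmA) - hmmLength(mods$hmmB), 70L)
  # motif columns carry much lower emission entropy than plain columns
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  entA <- apply(matchEmissions(mods$hmmA), 1, ent)
  motif_cols <- c(16, 18, 21, 83, 275, 277, 279, 280, 349)
  expect_lt(max(entA[motif_cols]), min(entA[-c(1, motif_cols)]))
  # sampled A proteins carry an N-terminal GxGxxG in nearly every draw
  hits <- vapply(1:60, function(i) {
    s <- sampleSequence(mods$hmmA, 3000 + i)
    h <- scanMotifs(s, defaultMotifs()[1, , drop = FALSE])
    any(h$start >= 10 & h$start <= 30)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # reproducibility
  m2 <- makeReferenceModels(1699)
  expect_equal(matchEmissions(m2$hmmA), matchEmissions(mods$hmmA))
  expect_identical(as.character(m2$seedA), as.character(mods$seedA))
})

test_that("the benchmark manifest echoes the configured cohort", {
  cfg <- benchmarkConfig(nCompleteA = 4L, nCompleteB = 3L, nPartial = 4L,
                         nDecoys = 4L, seed = 7L)
  b <- makeBenchmark(cfg)
  man <- b$manifest
  expect_equal(nrow(man), 15L)
  expect_equal(sum(man$class == "A" & man$completeness == "complete"), 4L)
  expect_equal(sum(man$class == "B" & man$completeness == "complete"), 3L)
  expect_equal(sum(man$completeness == "partial" & man$class != "decoy"), 4L)
  expect_equal(sum(man$class == "decoy"), 4L)
  # coordinates lie within their host contigs
  w <- setNames(Biostrings::width(b$contigs), names(b$contigs))
  expect_true(all(man$start >= 1 & man$end <= w[man$contig]))
  # default cohort echoes the familiar shape: 42 complete A, 254 elements
  dc <- benchmarkConfig()
  expect_equal(dc$nCompleteA, 42L)
  expect_equal(dc$nCompleteA + dc$nCompleteB + dc$nPartial + dc$nDecoys, 254L)
})

test_that("benchmarks are byte-identical for a fixed seed", {
  cfg <- benchmarkConfig(nCompleteA = 2L, nCompleteB = 2L, nPartial = 2L,
                         nDecoys = 2L, nBackgroundContigs = 2L, seed = 11L)
  b1 <- makeBenchmark(cfg)
  b2 <- makeBenchmark(cfg)
  expect_identical(as.character(b1$contigs), as.character(b2$contigs))
  expect_identical(b1$manifest, b2$manifest)
  tf <- withr::local_tempfile(fileext = ".json")
  writeManifest(b1$manifest, tf)
  back <- readManifest(tf)
  expect_equal(back$start, b1$manifest$start)
  expect_equal(back$class, b1$manifest$class)
})

test_that("planted complete genes outscore the decoy score distribution", {
  cfg <- benchmarkConfig(nCompleteA = 3L, nCompleteB = 2L, nPartial = 0L,
                         nDecoys = 0L, nBackgroundContigs = 0L, seed = 13L)
  b <- makeBenchmark(cfg)
  hmm <- calibrateHmm(b$models$hmmA, nDecoys = 100, decoyLength = 300,
                      seed = 13L)
  fit <- calibration(hmm)
  # decoy 99.9th percentile under the fitted Gumbel
  q999 <- fit@mu - log(-log(0.999)) / fit@lambda
  for (i in seq_len(nrow(b$manifest))) {
    p <- b$manifest[i, ]
    nt <- substr(as.character(b$contigs[[p$contig]]), p$start, p$end)
    if (p$strand == "-")
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    prot <- translateCds(nt)
    expect_gt(forwardBits(hmm, prot), q999)
  }
})

test_that("monooxygenase-like decoys keep GxGxxG but lack WxWxIP", {
  cfg <- benchmarkConfig(nCompleteA = 0L, nCompleteB = 0L, nPartial = 0L,
                         nDecoys = 6L, nBackgroundContigs = 0L, seed = 17L)
  b <- makeBenchmark(cfg)
  mono <- b$manifest[b$manifest$decoy_type == "monooxygenase", ]
  expect_gt(nrow(mono), 0L)
  for (i in seq_len(nrow(mono))) {
    p <- mono[i, ]
    nt <- substr(as.character(b$contigs[[p$contig]]), p$start, p$end)
    if (p$strand == "-")
      nt <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(nt)))
    hits <- scanMotifs(translateCds(nt))
    expect_false("WxWxIP" %in% hits$motif)
    expect_true("GxGxxG" %in% hits$motif)
  }
})

test_that("recovery scoring implements the 80% overlap rule", {
  man <- data.frame(element_id = paste0("e", 1:10),
                    contig = paste0("c", 1:10),
                    start = 101L, end = 1600L, strand = "+",
                    class = rep(c("A", "B"), 5),
                    completeness = "complete",
                    decoy_type = NA_character_,
                    protein_length = 499L, source_model = "synthA",
                    stringsAsFactors = FALSE)
  perfect <- data.frame(contig = man$contig, start = man$start,
                        end = man$end, strand = "+",
                        evalue_pass = TRUE, complete = TRUE,
                        stringsAsFactors = FALSE)
  sc <- scoreRecovery(perfect, man)
  expect_true(all(sc$recall$recall == 1))
  expect_equal(sc$precision, 1)
  expect_equal(sc$decoy_false_positives, 0L)
  # drop one of ten: recall 0.9 overall
  sc2 <- scoreRecovery(perfect[-1, ], man)
  expect_equal(sum(sc2$recall$recovered) / sum(sc2$recall$n), 0.9)
  # a candidate covering only half the span does not count
  half <- perfect
  half$end <- man$start + floor(0.5 * (man$end - man$start))
  sc3 <- scoreRecovery(half, man)
  expect_true(all(sc3$recall$recall == 0))
  expect_error(scoreRecovery(data.frame(contig = "zz", start = 1, end = 2,
                                        strand = "+", evalue_pass = TRUE,
                                        complete = TRUE), man),
               "mismatched")
})
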