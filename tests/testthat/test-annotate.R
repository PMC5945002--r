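test_that("the BrvH-like stand-in carries the published anchor layout", {
  prot <- as.character(brvhStandin())[[1]]
  expect_equal(nchar(prot), 509L)
  hits <- scanMotifs(prot)
  g <- hits[hits$motif == "GxGxxG", ]
  w <- hits[hits$motif == "WxWxIP", ]
  expect_equal(g$start[1], 16L)
  expect_equal(g$end[1], 21L)
  expect_equal(w$start[1], 275L)
  expect_equal(w$end[1], 280L)
  expect_identical(substr(prot, 83, 83), "K")
  expect_identical(substr(prot, 349, 349), "E")
})

test_that("motif scanning matches patterns literally and reports overlaps", {
  hits <- scanMotifs("GAGAAGAAAA")
  expect_equal(hits$start[hits$motif == "GxGxxG"][1], 1L)
  expect_equal(nrow(scanMotifs(strrep("L", 300))), 0L)
  # overlapping occurrences are all reported
  hits2 <- scanMotifs("GGGGGGGG")
  expect_equal(sum(hits2$motif == "GxGxxG"), 3L)
})

test_that("motif scanning agrees with a naive position checker", {
  set.seed(21)
  motifs <- defaultMotifs()
  for (i in 1:15) {
    s <- paste(sample(c(AA, "G", "W", "I", "P"), 120, replace = TRUE),
               collapse = "")
    got <- scanMotifs(s, motifs)
    for (m in seq_len(nrow(motifs))) {
      expect_identical(got$start[got$motif == motifs$name[m]],
                       naive_motif_scan(s, motifs$pattern[m]))
    }
  }
})

test_that("catalytic-residue mapping is the identity on training rows", {
  prot <- as.character(brvhStandin())[[1]]
  set.seed(22)
  # companion rows: the stand-in with scattered substitutions
  mutate <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(setdiff(seq_along(ch), c(16, 18, 21, 83, 275, 277, 279,
                                           280, 349)), n)
    ch[idx] <- vapply(ch[idx], function(a) sample(setdiff(AA, a), 1), "")
    paste(ch, collapse = "")
  }
  msa <- Biostrings::AAStringSet(c(brvh = prot, m1 = mutate(prot, 60),
                                   m2 = mutate(prot, 60)))
  h <- buildHmm(msa)
  anchors <- data.frame(ref = "brvh", position = c(83L, 349L),
                        residue = c("K", "E"))
  res <- mapCatalyticResidues(prot, h, anchors)
  expect_equal(res$mapped_position, c(83L, 349L))
  expect_true(all(res$match))
  # a query with the anchored column deleted maps to nothing
  del <- paste0(substr(prot, 1, 80), substr(prot, 87, nchar(prot)))
  res2 <- mapCatalyticResidues(del, h, anchors[1, , drop = FALSE])
  expect_true(is.na(res2$mapped_position) || res2$observed != "K")
  expect_error(mapCatalyticResidues(prot, h,
                                    data.frame(ref = "brvh",
                                               position = 99999L,
                                               residue = "K")),
               "outside")
})

test_that("completeness verdicts follow the four criteria with reasons", {
  cfg <- completenessConfig()
  hits <- data.frame(motif = c("GxGxxG", "WxWxIP"), start = c(16L, 275L),
                     end = c(21L, 280L), matched = c("GAGAAG", "WAWAIP"))
  ok <- assessCompleteness(TRUE, TRUE, 530L, hits, 1e-60, cfg)
  expect_true(ok$complete)
  expect_length(ok$reasons, 0L)
  trunc <- assessCompleteness(TRUE, FALSE, 530L, hits, 1e-60, cfg)
  expect_false(trunc$complete)
  expect_match(trunc$reasons, "start_stop")
  nom <- assessCompleteness(TRUE, TRUE, 530L, hits[1, ], 1e-60, cfg)
  expect_false(nom$complete)
  expect_match(nom$reasons, "WxWxIP")
  short <- assessCompleteness(TRUE, TRUE, 120L, hits, 1e-60, cfg)
  expect_match(short$reasons, "length")
  weak <- assessCompleteness(TRUE, TRUE, 530L, hits, 1e-2, cfg)
  expect_match(weak$reasons, "evalue")
})

test_that("relaxing any single criterion never revokes completeness", {
  set.seed(23)
  hits_all <- data.frame(motif = c("GxGxxG", "WxWxIP"), start = c(1L, 10L),
                         end = c(6L, 15L), matched = c("GAGAAG", "WAWAIP"))
  # a known-complete gene stays complete under every single-criterion
  # relaxation
  for (rc in list(completenessConfig(requireStart = FALSE),
                  completenessConfig(requiredMotifs = "GxGxxG"),
                  completenessConfig(lenMax = 1000L),
                  completenessConfig(evalueMax = 1))) {
    expect_true(assessCompleteness(TRUE, TRUE, 530L, hits_all, 1e-60,
                                   rc)$complete)
  }
  for (i in 1:30) {
    hs <- sample(c(TRUE, FALSE), 1); hp <- sample(c(TRUE, FALSE), 1)
    len <- sample(c(100L, 500L, 700L), 1)
    ev <- sample(c(1e-60, 1e-3), 1)
    hits <- hits_all[seq_len(sample(0:2, 1)), , drop = FALSE]
    cfg <- completenessConfig()
    base <- assessCompleteness(hs, hp, len, hits, ev, cfg)$complete
    relaxed <- list(
      completenessConfig(requireStart = FALSE, requireStop = FALSE),
      completenessConfig(requiredMotifs = character(0)),
      completenessConfig(lenMin = 1L, lenMax = 10000L),
      completenessConfig(evalueMax = 1e6))
    for (rc in relaxed) {
      r <- assessCompleteness(hs, hp, len, hits, ev, rc)$complete
      if (base) expect_true(r)
    }
  }
})
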