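test_that("model construction follows the stated estimation rules", {
  rows <- c(s1 = "MKV", s2 = "MKV", s3 = "MKV", s4 = "MKV")
  h <- buildHmm(Biostrings::AAStringSet(rows))
  expect_equal(hmmLength(h), 3L)
  expect_identical(AA[apply(matchEmissions(h), 1, which.max)],
                   c("M", "K", "V"))
  # pseudocount rule: emission = (count + w * bg) / (n + w)
  rows2 <- c(a = "A", b = "A", c = "A", d = "C")
  h2 <- buildHmm(Biostrings::AAStringSet(rows2), pseudocountWeight = 2)
  bg <- backgroundFreqs(h2)
  em <- unname(matchEmissions(h2)[1, ])
  expect_equal(em[match("A", AA)], (3 + 2 * bg[["A"]]) / (4 + 2))
  expect_equal(em[match("C", AA)], (1 + 2 * bg[["C"]]) / (4 + 2))
  expect_equal(em[match("W", AA)], (0 + 2 * bg[["W"]]) / (4 + 2))
})

test_that("occupancy threshold decides match columns", {
  # column 2: 40% gaps -> match at threshold 0.5; column 3: 60% gaps -> not
  rows <- c(a = "M-KV", b = "MA-V", c = "MA-V", d = "MA-V", e = "M-KV")
  m <- do.call(rbind, strsplit(rows, ""))
  occ <- colMeans(m != "-")
  expect_equal(occ, c(1, 0.6, 0.4, 1))
  h <- buildHmm(Biostrings::AAStringSet(rows), occupancyThreshold = 0.5)
  expect_equal(hmmLength(h), 3L)  # columns 1, 2, 4
  expect_error(buildHmm(Biostrings::AAStringSet(c(a = "-", b = "-"))),
               "occupancy")
})

test_that("emission and transition bundles renormalise to one", {
  set.seed(11)
  for (i in 1:5) {
    h <- random_tiny_hmm(max_L = 10)
    if (is.null(h)) next
    expect_true(validObject(h))
  }
})

test_that("a sure one-state emitter scores log2(1/background) closed form", {
  h <- unit_hmm("K")
  expect_equal(forwardBits(h, "K"), log2(20))
  v <- viterbiAlign(h, "K")
  expect_equal(v$bits, log2(20))
  expect_equal(v$map, 1L)
})

test_that("Forward and Viterbi equal exhaustive path enumeration", {
  set.seed(12)
  n_checked <- 0
  while (n_checked < 40) {
    h <- random_tiny_hmm(max_L = 3)
    if (is.null(h)) next
    for (j in 1:4) {
      s <- random_protein(sample(1:4, 1))
      expect_equal(forwardBits(h, s), enum_paths(h, s, "sum"),
                   tolerance = 1e-9)
      expect_equal(viterbiAlign(h, s)$bits, enum_paths(h, s, "max"),
                   tolerance = 1e-9)
      n_checked <- n_checked + 1
    }
  }
})

test_that("Forward dominates Viterbi everywhere", {
  set.seed(13)
  for (i in 1:15) {
    h <- random_tiny_hmm(max_L = 10)
    if (is.null(h)) next
    s <- random_protein(sample(3:12, 1))
    expect_gte(forwardBits(h, s) + 1e-9, viterbiAlign(h, s)$bits)
  }
})

test_that("Viterbi maps the training sequence onto itself and flags inserts", {
  s <- "MKVLADEQHW"
  h <- buildHmm(Biostrings::AAStringSet(c(a = s, b = s)),
                pseudocountWeight = 0.01)
  v <- viterbiAlign(h, s)
  expect_equal(v$map, 1:10)
  expect_equal(v$n_insert, 0L)
  # one inserted residue relative to the trained consensus
  v2 <- viterbiAlign(h, "MKVLAWDEQHW")
  expect_equal(v2$n_insert, 1L)
})

test_that("sampling is deterministic per seed and degenerate models give consensus", {
  rows <- c(a = "MKVLAD", b = "MKVLAD")
  h <- buildHmm(Biostrings::AAStringSet(rows), pseudocountWeight = 1e-12)
  expect_identical(sampleSequence(h, 1), "MKVLAD")
  set.seed(99)  # global RNG must not affect the draw
  a <- sampleSequence(h, 42); b <- sampleSequence(h, 42)
  expect_identical(a, b)
})

test_that("model draws score higher than their shuffles", {
  mods <- makeReferenceModels(1699)
  h <- mods$hmmA
  set.seed(14)
  draws <- vapply(1:15, function(i)
    sampleSequence(h, 1000 + i), "")
  d_bits <- vapply(draws, function(s) forwardBits(h, s), 0)
  s_bits <- vapply(draws, function(s)
    forwardBits(h, paste(sample(strsplit(s, "")[[1]]), collapse = "")), 0)
  expect_gt(median(d_bits), median(s_bits))
  expect_true(all(d_bits > s_bits))
})

test_that("Gumbel ML fitting recovers known parameters within 5%", {
  set.seed(15)
  mu <- 5; lam <- 0.7
  x <- mu - log(-log(runif(2000))) / lam
  fit <- fitGumbel(x)
  expect_lt(abs(fit$mu - mu) / mu, 0.05)
  expect_lt(abs(fit$lambda - lam) / lam, 0.05)
  expect_error(fitGumbel(rep(1, 200)), "degenerate")
})

test_that("E-values respect tail limits and quantile consistency", {
  fit <- new("GumbelFit", mu = 5, lambda = 0.7, nDecoys = 1000L,
             decoyLength = 100L, seed = 1L)
  expect_equal(evalueFromFit(fit, 1e6, 5000), 0)
  expect_equal(evalueFromFit(fit, -1e6, 5000), 5000)
  expect_true(all(diff(evalueFromFit(fit, seq(-10, 60, 5), 100)) <= 0))
  # empirical 95th percentile of Gumbel draws maps to E ~ 0.05 * dbSize
  set.seed(16)
  x <- 5 - log(-log(runif(4000))) / 0.7
  q95 <- quantile(x, 0.95)
  ev <- evalueFromFit(fit, q95, 1)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(ev - 0.05), 3 * se)
})

test_that("calibration attaches a valid fit and separates true hits", {
  mods <- makeReferenceModels(1699)
  h <- calibrateHmm(mods$hmmB, nDecoys = 120, decoyLength = 150, seed = 2)
  fit <- calibration(h)
  expect_s4_class(fit, "GumbelFit")
  expect_gt(fit@lambda, 0)
  s <- sampleSequence(h, 3)
  expect_lt(evalueFromFit(fit, forwardBits(h, s), 1e6), 1e-20)
})

test_that("JSON serialization round-trips models and scores", {
  set.seed(17)
  h <- buildHmm(Biostrings::AAStringSet(
    c(a = "MKVLAD-Q", b = "MKVLADEQ", c = "MKV-ADEQ")))
  h <- calibrateHmm(h, nDecoys = 100, decoyLength = 30, seed = 4)
  tf <- withr::local_tempfile(fileext = ".json")
  writeHmmJson(h, tf)
  h2 <- readHmmJson(tf)
  expect_equal(hmmLength(h2), hmmLength(h))
  s <- random_protein(12)
  expect_equal(forwardBits(h2, s), forwardBits(h, s), tolerance = 1e-12)
  expect_equal(calibration(h2)@mu, calibration(h)@mu)
  expect_equal(h2@refMap, h@refMap)
})
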