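test_that("p-distances count mismatches with pairwise deletion", {
  msa <- Biostrings::AAStringSet(c(a = "MKVLADEQHW", b = "MKVLADEQHW",
                                   c = "MKVLADEQHW"))
  d <- pDistanceMatrix(msa)
  expect_true(all(d == 0))
  msa2 <- Biostrings::AAStringSet(c(a = "MKVLADEQHW", b = "MKVLWWWQHW",
                                    c = "MKVLADEQHW"))
  expect_equal(pDistanceMatrix(msa2)["a", "b"], 0.3)
  # counting oracle on random gapped alignments
  set.seed(31)
  for (rep in 1:6) {
    n <- sample(3:6, 1); nc <- sample(10:30, 1)
    rows <- replicate(n, {
      ch <- sample(AA, nc, replace = TRUE)
      ch[runif(nc) < 0.15] <- "-"
      paste(ch, collapse = "")
    })
    names(rows) <- paste0("t", seq_len(n))
    m <- do.call(rbind, strsplit(rows, ""))
    rownames(m) <- names(rows)
    ok <- TRUE
    want <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      comp <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(comp)) { ok <- FALSE; break }
      want[i, j] <- want[j, i] <- mean(m[i, comp] != m[j, comp])
    }
    if (!ok) next
    got <- pDistanceMatrix(Biostrings::AAStringSet(rows))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
  # Poisson correction
  expect_equal(pDistanceMatrix(msa2, "poisson")["a", "b"], -log(1 - 0.3))
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- njTree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(bl["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(bl["C"]), (4 + 5 - 3) / 2)
})

test_that("NJ exactly recovers random additive trees", {
  set.seed(32)
  for (i in 1:25) {
    n <- sample(6:10, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    d <- ape::cophenetic.phylo(tr)
    got <- njTree(d[tr$tip.label, tr$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(got), tr), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(got)[tr$tip.label, tr$tip.label],
                 d, tolerance = 1e-8)
  }
})

test_that("NJ topology is invariant to taxon order", {
  set.seed(33)
  tr <- ape::unroot(ape::rtree(8, br = function(k) runif(k, 0.1, 1)))
  d <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(d))
  t1 <- njTree(d)
  t2 <- njTree(d[perm, perm])
  expect_equal(ape::dist.topo(t1, t2), 0, ignore_attr = TRUE)
  expect_error(njTree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("unanimous signal earns full bootstrap support", {
  msa <- Biostrings::AAStringSet(c(
    a1 = strrep("A", 30), a2 = strrep("A", 30),
    b1 = strrep("C", 30), b2 = strrep("C", 30)))
  tr <- bootstrapSupport(msa, nReps = 100, seed = 5)
  labs <- suppressWarnings(as.integer(tr$node.label))
  expect_true(any(labs == 100, na.rm = TRUE))
})

test_that("bootstrap defaults to 1000 replicates", {
  expect_equal(eval(formals(bootstrapSupport)$nReps), 1000L)
})

test_that("bootstrap supports are reproducible and seed-consistent", {
  set.seed(34)
  rows <- vapply(1:6, function(i) {
    base <- if (i <= 3) random_protein(40) else random_protein(40)
    base
  }, "")
  # two related blocks with internal similarity
  a <- random_protein(40)
  b <- random_protein(40)
  mut <- function(s, k) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(40, k)
    ch[idx] <- vapply(ch[idx], function(x) sample(setdiff(AA, x), 1), "")
    paste(ch, collapse = "")
  }
  msa <- Biostrings::AAStringSet(c(a1 = a, a2 = mut(a, 4), a3 = mut(a, 4),
                                   b1 = b, b2 = mut(b, 4), b3 = mut(b, 4)))
  t1 <- bootstrapSupport(msa, nReps = 200, seed = 7)
  t2 <- bootstrapSupport(msa, nReps = 200, seed = 7)
  expect_identical(t1$node.label, t2$node.label)
  t3 <- bootstrapSupport(msa, nReps = 200, seed = 8)
  s1 <- suppressWarnings(as.integer(t1$node.label))
  s3 <- suppressWarnings(as.integer(t3$node.label))
  # different seeds agree within binomial sampling error on strong edges
  expect_true(all(abs(s1 - s3) <= 20, na.rm = TRUE))
})

test_that("variant classification uses clades first and length second", {
  # query inside a pure A clade
  tr <- ape::read.tree(text = paste0(
    "(((q:0.05,A1:0.05):0.1,(A2:0.05,A3:0.05):0.1):0.3,",
    "(B1:0.05,(B2:0.05,B3:0.05):0.1):0.3);"))
  call <- classifyVariant(tr, c("A1", "A2", "A3"), c("B1", "B2", "B3"), "q")
  expect_equal(call$call, "A")
  expect_equal(call$evidence, "clade")
  # query identical to a B reference (zero-length cherry)
  tr2 <- ape::read.tree(text = paste0(
    "((A1:0.1,A2:0.1):0.3,((q:0,B1:0):0.1,B2:0.1):0.3);"))
  call2 <- classifyVariant(tr2, c("A1", "A2"), c("B1", "B2"), "q")
  expect_equal(call2$call, "B")
  # every query-containing side is mixed: only the length prior can decide
  tr3 <- ape::read.tree(text =
    "(q:0.1,(A1:0.1,B1:0.1):0.1,(A2:0.1,B2:0.1):0.1);")
  call3 <- classifyVariant(tr3, c("A1", "A2"), c("B1", "B2"), "q",
                           queryLength = 465,
                           refLengths = c(A1 = 535, A2 = 535,
                                          B1 = 465, B2 = 466))
  expect_equal(call3$evidence, "length_prior")
  expect_equal(call3$call, "B")
  expect_error(classifyVariant(tr, c("A1", "A2"), c("B1", "B2"), "zz"),
               "absent")
})
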