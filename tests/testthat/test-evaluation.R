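uniformFolds <- function(nFolds, M, seed) {
  set.seed(seed)
  data.frame(heldOut = sprintf("f%03d", seq_len(nFolds)), M = M,
             R = sample.int(M, nFolds, replace = TRUE), absent = FALSE)
}

test_that("two adjacent seeds recover each other at rank 1", {
  g <- readPPITable(tmpLines("s1\ts2\t0.8"))
  folds <- loocv(g, seedSet(c("s1", "s2")))
  expect_equal(nrow(folds), 2L)
  expect_equal(folds$R, c(1L, 1L))
  expect_equal(folds$M, c(1L, 1L))
  expect_false(any(folds$absent))
  expect_error(loocv(g, seedSet("s1")), "at least 2 seeds")
})

test_that("a held-out seed with no remaining-seed neighbor takes the sentinel", {
  ## s3 touches only candidate c, never s1/s2: held out, it cannot re-enter
  g <- readPPITable(tmpLines(c("s1\ts2\t0.9", "s1\ta\t0.5", "s3\tc\t0.5")))
  folds <- loocv(g, seedSet(c("s1", "s2", "s3")))
  f3 <- folds[folds$heldOut == "s3", ]
  expect_true(f3$absent)
  expect_equal(f3$R, f3$M)         # sentinel: worst rank M+1 with M bumped
  expect_true(all(folds$R >= 1 & folds$R <= folds$M))
})

test_that("loocv produces one fold per seed, independent of seed order", {
  g <- randomGraph(40, 0.2, seed = 2)
  ids <- sort(sample(graphNodes(g), 6))
  f1 <- loocv(g, seedSet(ids))
  f2 <- loocv(g, seedSet(rev(ids)))
  expect_equal(nrow(f1), 6L)
  expect_identical(f1, f2)
})

test_that("loocv equals an independent fold-by-fold rebuild and re-score", {
  s <- simulateStudy(seed = 7)
  corpus <- studyCorpus(s)
  fsim <- similarityProvider(corpus)
  g <- studyGraph(s)
  folds <- loocv(g, studySeeds(s), corpus, scoreParams(2, 3))
  members <- sort(seedMembers(studySeeds(s)))
  for (i in seq_along(members)) {
    rem <- seedSet(setdiff(members, members[i]), label = "synthetic")
    net <- buildDiseaseNetwork(g, rem, fsim = fsim)
    rc <- rankedCandidates(scoreAll(net, g, scoreParams(2, 3), fsim = fsim))
    R <- rc$rank[match(members[i], rc$protein)]
    M <- nrow(rc)
    if (is.na(R)) { M <- M + 1L; R <- M }
    expect_equal(folds$R[i], R)
    expect_equal(folds$M[i], M)
  }
})

test_that("the rank-ratio ROC hits its limits and the chance line", {
  top <- data.frame(heldOut = sprintf("f%d", 1:50), M = 1000L, R = 1L,
                    absent = FALSE)
  expect_gte(rocAUC(rocFromFolds(top)), 0.999)
  bottom <- transform(top, R = 1000L)
  expect_lte(rocAUC(rocFromFolds(bottom)), 0.001)
  unif <- uniformFolds(200, 100L, seed = 31)
  expect_equal(rocAUC(rocFromFolds(unif)), 0.5, tolerance = 0.1)
  expect_true(abs(rocAUC(rocFromFolds(unif)) - 0.5) <= 0.05)
})

test_that("ROC curves span the unit square and invert with the ranking", {
  for (s in 1:5) {
    folds <- uniformFolds(40, 60L, seed = s)
    roc <- rocFromFolds(folds)
    p <- rocPoints(roc)
    expect_equal(p$fpr[1], 0); expect_equal(p$tpr[1], 0)
    expect_equal(p$fpr[nrow(p)], 1); expect_equal(p$tpr[nrow(p)], 1)
    expect_true(rocAUC(roc) >= 0 && rocAUC(roc) <= 1)
    rev <- transform(folds, R = M - R + 1L)
    expect_equal(rocAUC(rocFromFolds(rev)), 1 - rocAUC(roc),
                 tolerance = 1 / min(folds$M))
  }
  ## macro averaging stays a valid curve
  roc <- rocFromFolds(uniformFolds(40, 60L, seed = 9), average = "macro")
  expect_s4_class(roc, "RocCurve")
})

test_that("AUC comparison orders methods and breaks ties by name", {
  mk <- function(auc) new("RocCurve",
                          points = data.frame(fpr = c(0, 1), tpr = c(0, 1)),
                          auc = auc, nFolds = 10L)
  cmp <- aucCompare(list(m2 = mk(0.7), m1 = mk(0.9)))
  expect_equal(cmp$method, c("m1", "m2"))
  expect_equal(aucCompare(list(only = mk(0.5)))$method, "only")
  tie <- aucCompare(list(zeta = mk(0.6), alpha = mk(0.6)))
  expect_equal(tie$method, c("alpha", "zeta"))
})

test_that("external rankings become pseudo-folds for comparison", {
  ranking <- data.frame(protein = c("a", "b", "c", "d"), rank = 1:4)
  folds <- foldsFromRanking(ranking, positives = c("b", "zz"))
  expect_equal(folds$R[folds$heldOut == "b"], 2L)
  f2 <- folds[folds$heldOut == "zz", ]
  expect_true(f2$absent)
  expect_equal(f2$R, 5L)
})

test_that("hypergeometric enrichment matches closed cases and flags significance", {
  sets <- geneSetCollection(list(hit = sprintf("u%02d", 1:5)),
                            universe = sprintf("u%02d", 1:20))
  ## all five drawn from the five-member set: p = 1/C(20,5)
  r <- hypergeomEnrichment(sprintf("u%02d", 1:5), sets)
  expect_equal(r$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_true(r$significant)
  expect_equal(r$k, 5L)
  ## no overlap: upper tail includes X >= 0 so p = 1
  r0 <- hypergeomEnrichment(sprintf("u%02d", 6:10), sets)
  expect_equal(r0$p, 1)
  ## set equal to the universe: p = 1
  all <- geneSetCollection(list(everything = sprintf("u%02d", 1:20)),
                           universe = sprintf("u%02d", 1:20))
  expect_equal(hypergeomEnrichment(sprintf("u%02d", 1:3), all)$p, 1)
  ## out-of-universe ids are rejected by name
  expect_error(hypergeomEnrichment(c("u01", "alien"), sets), "alien")
  ## BH column on request
  rBH <- hypergeomEnrichment(sprintf("u%02d", 1:5), sets, adjust = "BH")
  expect_true("p_adjusted" %in% colnames(rBH))
})

test_that("hypergeometric p equals exhaustive enumeration for small universes", {
  for (N in c(5L, 8L, 12L)) {
    for (K in unique(c(1L, N %/% 2, N - 1L))) {
      for (n in unique(c(1L, N %/% 2))) {
        for (k in 0:min(K, n)) {
          if (K + (n - k) > N) next      # not constructible
          universe <- sprintf("x%02d", seq_len(N))
          sets <- geneSetCollection(list(s = universe[seq_len(K)]),
                                    universe = universe)
          top <- c(universe[seq_len(k)],
                   universe[K + seq_len(n - k)])
          if (length(top) != n || anyDuplicated(top)) next
          got <- hypergeomEnrichment(top, sets)$p
          expect_equal(got, oracleHyperP(N, K, n, k), tolerance = 1e-10)
        }
      }
    }
  }
})

test_that("seed-set overlap reports shared members deterministically", {
  a <- seedSet(c("z", "m", "k"), label = "A")
  b <- seedSet(c("k", "z", "q"), label = "B")
  ov <- setOverlap(a, b)
  expect_equal(ov$shared, c("k", "z"))
  expect_equal(ov$nShared, 2L)
  expect_equal(setOverlap(a, a)$nShared, 3L)
  expect_equal(setOverlap(a, seedSet("w"))$nShared, 0L)
})
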