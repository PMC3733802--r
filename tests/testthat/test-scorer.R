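pairInvolves <- function(a, b, x, y) (a == x && b == y) || (a == y && b == x)

test_that("the worked two-neighbor example and the empty case score as stated", {
  ## i has an in-network neighbor s (C = 0.9, F = 0.5) and an
  ## out-of-network neighbor j2 (C = 0.8, F -> fallback 0):
  ## S(i) = (0.9 + 0.5) - (0.8 + 0) = 0.6 at alpha = beta = 1
  g <- readPPITable(tmpLines(c("s\ti\t0.9", "i\tj2\t0.8")))
  fsim <- function(a, b) if (pairInvolves(a, b, "s", "i")) 0.5 else 0
  net <- buildDiseaseNetwork(g, seedSet("s"), fsim = fsim)
  expect_equal(diseaseRelevanceScore("i", net, g, scoreParams(1, 1),
                                     fsim = fsim), 0.6)

  ## isolated protein: empty sums give 0
  g2 <- weightedPPIGraph(graphEdges(g), extraNodes = "lonely")
  net2 <- buildDiseaseNetwork(g2, seedSet(c("s", "lonely")))
  expect_equal(diseaseRelevanceScore("lonely", net2, g2), 0)

  expect_error(diseaseRelevanceScore("nope", net, g), "not in the disease")
})

test_that("scoreAll matches the naive double-loop oracle on random graphs", {
  for (s in 1:8) {
    g <- randomGraph(sample(20:60, 1), 0.15, seed = s)
    seeds <- seedSet(sort(sample(graphNodes(g), 5)))
    net <- suppressWarnings(buildDiseaseNetwork(g, seeds))
    params <- scoreParams(alpha = 3, beta = 7)
    set.seed(s + 100)
    fvals <- new.env()
    fsim <- function(a, b) {
      k <- paste(sort(c(a, b)), collapse = "|")
      if (is.null(fvals[[k]])) fvals[[k]] <- runif(1)
      fvals[[k]]
    }
    net <- buildDiseaseNetwork(g, seeds, fsim = fsim)
    st <- scoreAll(net, g, params, fsim = fsim)
    oracle <- oracleScores(net, g, 3, 7, fsim = fsim)
    got <- setNames(scoreTable(st)$score, scoreTable(st)$protein)
    expect_equal(got[names(oracle)], oracle, tolerance = 1e-9)
  }
})

test_that("ranks are candidate-only, descending, with lexicographic ties", {
  ## scores: a = 1.0, b = 0.4, c = 0.4 -> ranks a=1, b=2, c=3
  g <- readPPITable(tmpLines(c("s\ta\t1.0", "s\tc\t0.4", "s\tb\t0.4")))
  st <- scoreAll(buildDiseaseNetwork(g, seedSet("s")), g)
  rc <- rankedCandidates(st)
  expect_equal(rc$protein, c("a", "b", "c"))
  expect_equal(rc$rank, 1:3)
  ## the seed is scored but not ranked
  tb <- scoreTable(st)
  expect_true(is.na(tb$rank[tb$protein == "s"]))
  expect_false(is.na(tb$score[tb$protein == "s"]))

  ## empty candidate set -> empty rank table
  g2 <- readPPITable(tmpLines("s1\ts2\t0.8"))
  st2 <- scoreAll(buildDiseaseNetwork(g2, seedSet(c("s1", "s2"))), g2)
  expect_equal(nrow(rankedCandidates(st2)), 0L)
})

test_that("neighbor additions move the score in the documented direction", {
  base <- c("s\ti\t0.9")
  g0 <- readPPITable(tmpLines(base))
  gIn <- readPPITable(tmpLines(c(base, "s\tk\t0.5", "i\tk\t0.3")))
  gOut <- readPPITable(tmpLines(c(base, "i\tq\t0.3")))
  s0 <- diseaseRelevanceScore("i", buildDiseaseNetwork(g0, seedSet("s")), g0)
  sIn <- diseaseRelevanceScore("i", buildDiseaseNetwork(gIn, seedSet("s")),
                               gIn)
  sOut <- diseaseRelevanceScore("i", buildDiseaseNetwork(gOut, seedSet("s")),
                                gOut)
  expect_gt(sIn, s0)     # new in-network neighbor k with C > 0
  expect_lt(sOut, s0)    # new out-of-network neighbor q
})

test_that("ranking is invariant under joint (alpha, beta) rescaling", {
  g <- randomGraph(40, 0.15, seed = 3)
  seeds <- seedSet(sort(sample(graphNodes(g), 5)))
  fsim <- function(a, b) abs(sin(nchar(paste(a, b)) + 1)) / 2
  net <- suppressWarnings(buildDiseaseNetwork(g, seeds, fsim = fsim))
  r1 <- rankedCandidates(scoreAll(net, g, scoreParams(2, 5), fsim = fsim))
  r2 <- rankedCandidates(scoreAll(net, g, scoreParams(6, 15), fsim = fsim))
  expect_equal(r1$protein, r2$protein)
  expect_equal(r1$rank, r2$rank)
})

test_that("a plugin formula supersedes the default", {
  g <- readPPITable(tmpLines(c("s\ti\t0.9", "i\tj\t0.8")))
  net <- buildDiseaseNetwork(g, seedSet("s"))
  degreeOnly <- function(nd, alpha, beta) sum(nd$I) - sum(1 - nd$I)
  p <- scoreParams(1, 1, formula = "plugin", plugin = degreeOnly)
  expect_equal(diseaseRelevanceScore("i", net, g, p), 0)  # one in, one out
  st <- scoreAll(net, g, p)
  tb <- scoreTable(st)
  expect_equal(tb$score[tb$protein == "i"], 0)
  expect_error(scoreParams(1, 1, formula = "plugin"), "plugin")
})
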