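test_that("annotation propagation closes under ancestors and counts usage", {
  corpus <- chainCorpus()
  ## g1 -> T:b1a propagates through T:b1 to the root
  expect_equal(propagatedAnnotations(corpus, "g1"),
               sort(c("T:b1a", "T:b1", "T:root")))
  expect_true(all(directAnnotations(corpus, "g1") %in%
                    propagatedAnnotations(corpus, "g1")))
  ## three of four genes reach T:b1; the root collects everyone
  expect_equal(unname(corpus@termCounts["T:b1"]), 3)
  expect_equal(unname(corpus@termCounts["T:root"]), 4)
  expect_equal(unname(corpus@namespaceSize["BP"]), 4)

  ## unknown terms are dropped with a warning
  expect_warning(
    c2 <- propagateAnnotations(chainDag(), list(gx = c("T:b1a", "T:nope"))),
    "absent from the ontology")
  expect_equal(directAnnotations(c2, "gx"), "T:b1a")
})

test_that("information content matches brute-force counting", {
  corpus <- chainCorpus()
  dag <- chainDag()
  direct <- list(g1 = "T:b1a", g2 = "T:b1b", g3 = "T:b1", g4 = "T:b2")
  ## root: p = 1 so IC = 0
  expect_equal(informationContent("T:root", corpus), 0)
  ## n(T:b2) = 1 of 4 -> ln 4; n(T:b1a) = 1 of 4 -> ln 4
  expect_equal(informationContent("T:b2", corpus), log(4))
  expect_equal(informationContent("T:b2", corpus),
               oracleIC(dag, direct, "T:b2"))
  ## n(T:b1) = 3 of 4
  expect_equal(informationContent("T:b1", corpus),
               oracleIC(dag, direct, "T:b1"))
  ## a two-of-four term via an independent corpus
  c2 <- propagateAnnotations(dag, list(a = "T:b1a", b = "T:b1b",
                                       c = "T:b2", d = "T:root"))
  expect_equal(informationContent("T:b1", c2), log(2))
})

test_that("term similarity honors the stated conventions", {
  corpus <- chainCorpus()
  cfg <- similarityConfig()
  ## identity with positive IC
  expect_equal(termSimilarity("T:b1a", "T:b1a", corpus, cfg), 1)
  ## both roots: IC sum zero -> 0 by convention
  expect_equal(termSimilarity("T:root", "T:root", corpus, cfg), 0)
  ## hand-enumerated Lin on the 5-term DAG
  dag <- chainDag()
  direct <- list(g1 = "T:b1a", g2 = "T:b1b", g3 = "T:b1", g4 = "T:b2")
  expect_equal(termSimilarity("T:b1a", "T:b1b", corpus, cfg),
               oracleLin(dag, direct, "T:b1a", "T:b1b"))
  expect_equal(termSimilarity("T:b1a", "T:b2", corpus, cfg),
               oracleLin(dag, direct, "T:b1a", "T:b2"))
  ## cross-namespace pairs are 0
  mixed <- ontologyDAG(
    data.frame(id = c("B:1", "M:1"), name = NA,
               namespace = c("BP", "MF"), stringsAsFactors = FALSE),
    data.frame(child = character(), parent = character(),
               relation = character()))
  cm <- propagateAnnotations(mixed, list(x = "B:1", y = "M:1"))
  expect_equal(termSimilarity("B:1", "M:1", cm, cfg), 0)
  ## resnik is normalized into [0,1]; rel is damped Lin
  expect_lte(termSimilarity("T:b1a", "T:b1b", corpus,
                            similarityConfig(termMeasure = "resnik")), 1)
  expect_lte(termSimilarity("T:b1a", "T:b1b", corpus,
                            similarityConfig(termMeasure = "rel")),
             termSimilarity("T:b1a", "T:b1b", corpus, cfg))
})

test_that("gene similarity equals the exhaustive best-match-average oracle", {
  dag <- chainDag()
  direct <- list(gA = c("T:b1a", "T:b2"), gB = c("T:b1b", "T:b1"),
                 gC = "T:b1a")
  corpus <- propagateAnnotations(dag, direct)
  cfg <- similarityConfig()
  for (pair in list(c("gA", "gB"), c("gA", "gC"), c("gB", "gC"))) {
    expect_equal(geneSimilarity(pair[1], pair[2], corpus, cfg),
                 min(1, oracleBMA(dag, direct, pair[1], pair[2])),
                 tolerance = 1e-12)
  }
  ## identical single-term annotation with positive IC -> exactly 1
  expect_equal(geneSimilarity("gC", "gC", corpus, cfg), 1)
  ## unannotated gene falls back to 0
  c2 <- propagateAnnotations(dag, c(direct, list(gZ = character())))
  expect_equal(geneSimilarity("gA", "gZ", c2, cfg), 0)
  expect_equal(geneSimilarity("gA", "missing", corpus, cfg), 0)
})

test_that("IC is anti-monotone and gene similarity symmetric/bounded on random corpora", {
  for (s in 1:20) {
    rc <- randomCorpus(s)
    ed <- ontologyEdges(rc$dag)
    icAll <- informationContent(ontologyTerms(rc$dag)$id, rc$corpus)
    names(icAll) <- ontologyTerms(rc$dag)$id
    usable <- !is.na(icAll)
    for (r in seq_len(nrow(ed))) {
      ch <- ed$child[r]; pa <- ed$parent[r]
      if (usable[ch] && usable[pa])
        expect_lte(icAll[pa], icAll[ch] + 1e-12)
    }
    genes <- annotatedGenes(rc$corpus)
    pick <- utils::head(genes, 4)
    for (g1 in pick) for (g2 in pick) {
      v12 <- geneSimilarity(g1, g2, rc$corpus)
      expect_gte(v12, 0); expect_lte(v12, 1)
      expect_equal(v12, geneSimilarity(g2, g1, rc$corpus))
    }
  }
})

test_that("the similarity provider agrees with direct computation", {
  rc <- randomCorpus(99)
  fsim <- similarityProvider(rc$corpus)
  genes <- annotatedGenes(rc$corpus)
  for (g1 in genes[1:4]) for (g2 in genes[5:8]) {
    expect_equal(fsim(g1, g2), geneSimilarity(g1, g2, rc$corpus),
                 tolerance = 1e-12)
  }
  ## matrix export is symmetric with unit diagonal where IC > 0
  m <- geneSimMatrix(genes[1:4], rc$corpus)
  expect_equal(m, t(m))
  expect_equal(dimnames(m), list(genes[1:4], genes[1:4]))
})
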