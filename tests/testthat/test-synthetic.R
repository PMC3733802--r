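test_that("the simulated ontology is a rooted DAG with a dedicated module subtree", {
  onto <- simulateOntology(simParams(), seed = 1)
  dag <- onto$dag
  expect_length(ontologyRoots(dag), 1L)
  expect_gte(length(onto$moduleTerms), 5L)
  ## acyclicity: construction already topologically sorts; assert anyway
  expect_s4_class(ontologyDAG(ontologyTerms(dag), ontologyEdges(dag)),
                  "OntologyDAG")
  ## minimal ontology: one root, two descendants
  p3 <- simParams(nTerms = 7L, moduleTermCount = 5L)
  d3 <- simulateOntology(p3, seed = 2)$dag
  expect_equal(nrow(ontologyTerms(d3)), 7L)
  expect_length(ontologyRoots(d3), 1L)
  ## determinism
  o2 <- simulateOntology(simParams(), seed = 1)
  expect_identical(ontologyEdges(onto$dag), ontologyEdges(o2$dag))
})

test_that("module genes draw from the module subtree, background from the rest", {
  p <- simParams()
  onto <- simulateOntology(p, seed = 4)
  genes <- sprintf("G%04d", 1:40)
  truth <- genes[1:10]
  ann <- simulateAnnotations(onto$dag, onto$moduleTerms, genes, truth, p,
                             seed = 4)
  for (g in truth) {
    expect_gte(length(ann[[g]]), 2L)
    expect_true(all(ann[[g]] %in% onto$moduleTerms))
  }
  bg <- setdiff(genes, truth)
  expect_false(any(unlist(ann[bg]) %in% onto$moduleTerms))
  ## with shared annotations disabled, module genes look like background
  p0 <- simParams(sharedAnnotations = FALSE)
  ann0 <- simulateAnnotations(onto$dag, onto$moduleTerms, genes, truth, p0,
                              seed = 4)
  expect_false(any(unlist(ann0[truth]) %in% onto$moduleTerms))
  ## determinism
  ann2 <- simulateAnnotations(onto$dag, onto$moduleTerms, genes, truth, p,
                              seed = 4)
  expect_identical(ann, ann2)
})

test_that("planted annotations create the within-module similarity signal", {
  withinMeans <- numeric(0); acrossMeans <- numeric(0)
  for (s in 1:20) {
    study <- simulateStudy(seed = s)
    corpus <- studyCorpus(study)
    fsim <- similarityProvider(corpus)
    truth <- studyTruth(study)
    bg <- setdiff(graphNodes(studyGraph(study)), truth)
    set.seed(s)
    tPairs <- t(replicate(15, sample(truth, 2)))
    xPairs <- cbind(sample(truth, 15, TRUE), sample(bg, 15))
    withinMeans <- c(withinMeans,
                     mean(mapply(fsim, tPairs[, 1], tPairs[, 2])))
    acrossMeans <- c(acrossMeans,
                     mean(mapply(fsim, xPairs[, 1], xPairs[, 2])))
  }
  expect_true(all(withinMeans > acrossMeans))
})

test_that("edge counts follow the planted probabilities", {
  p <- simParams()
  genes <- sprintf("G%04d", seq_len(p@nGenes))
  truth <- genes[seq_len(p@moduleSize)]
  withinCounts <- vapply(1:10, function(s) {
    g <- simulatePPI(p, genes, truth, seed = s)
    e <- graphEdges(g)
    sum(e$a %in% truth & e$b %in% truth)
  }, 0)
  expected <- p@pIn * choose(p@moduleSize, 2)          # 0.30 * 300 = 90
  sigma <- sqrt(choose(p@moduleSize, 2) * p@pIn * (1 - p@pIn))
  expect_lt(abs(mean(withinCounts) - expected), 3 * sigma)

  ## degenerate parameters: module clique, empty background
  pc <- simParams(pIn = 1, pOut = 0)
  gc <- simulatePPI(pc, genes, truth, seed = 1)
  e <- graphEdges(gc)
  expect_equal(nrow(e), choose(p@moduleSize, 2))
  expect_true(all(e$a %in% truth & e$b %in% truth))
  ## determinism
  expect_identical(graphEdges(simulatePPI(p, genes, truth, seed = 3)),
                   graphEdges(simulatePPI(p, genes, truth, seed = 3)))
})

test_that("a full study composes reproducibly with byte-identical fixtures", {
  s <- simulateStudy(seed = 42)
  expect_equal(length(graphNodes(studyGraph(s))), 200L)
  expect_length(studyTruth(s), 25L)
  expect_length(seedMembers(studySeeds(s)), 10L)
  expect_true(all(seedMembers(studySeeds(s)) %in% studyTruth(s)))

  d1 <- file.path(tempdir(), "study_a")
  d2 <- file.path(tempdir(), "study_b")
  writeStudy(s, d1)
  writeStudy(simulateStudy(seed = 42), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## the emitted fixtures are readable by the io module and faithful
  g2 <- readPPITable(file.path(d1, "ppi_edges.tsv"))
  expect_equal(nrow(graphEdges(g2)), nrow(graphEdges(studyGraph(s))))
  dag2 <- readOBO(file.path(d1, "ontology.obo"))
  expect_equal(nrow(ontologyTerms(dag2)), 60L)
  ann2 <- readGAF(file.path(d1, "annotations.gaf"))
  expect_identical(ann2[sort(names(ann2))],
                   s@annotations[sort(names(s@annotations))])
  seeds2 <- readSeedList(file.path(d1, "seeds.txt"))
  expect_equal(seedMembers(seeds2), seedMembers(studySeeds(s)))
  gmt <- readGMT(file.path(d1, "truth.gmt"))
  expect_setequal(gmt@sets$planted_module, studyTruth(s))
})

test_that("held-out module genes concentrate near the top of the ranking", {
  hits <- 0L
  for (s in 1:15) {
    study <- simulateStudy(seed = s)
    corpus <- studyCorpus(study)
    fsim <- similarityProvider(corpus)
    net <- buildDiseaseNetwork(studyGraph(study), studySeeds(study),
                               fsim = fsim)
    st <- scoreAll(net, studyGraph(study), scoreParams(1, 1), fsim = fsim)
    rc <- rankedCandidates(st)
    held <- intersect(setdiff(studyTruth(study),
                              seedMembers(studySeeds(study))), rc$protein)
    ratio <- rc$rank[match(held, rc$protein)] / nrow(rc)
    if (median(ratio) <= 0.20) hits <- hits + 1L
  }
  expect_gte(hits, 12L)
})
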