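## Shared in-code fixtures and independent oracles for the test suite.

tmpLines <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

## Small hand-specified ontology: root with two branches.
##   root -> b1 -> b1a, b1b ; root -> b2
chainDag <- function() {
  terms <- data.frame(
    id = c("T:root", "T:b1", "T:b1a", "T:b1b", "T:b2"),
    name = paste("term", 1:5),
    namespace = "BP", stringsAsFactors = FALSE)
  edges <- data.frame(
    child  = c("T:b1", "T:b1a", "T:b1b", "T:b2"),
    parent = c("T:root", "T:b1", "T:b1", "T:root"),
    relation = "is_a", stringsAsFactors = FALSE)
  ontologyDAG(terms, edges)
}

## Corpus over chainDag with hand-countable term usage.
chainCorpus <- function() {
  direct <- list(g1 = "T:b1a", g2 = "T:b1b", g3 = "T:b1", g4 = "T:b2")
  propagateAnnotations(chainDag(), direct)
}

## Independent ancestor enumeration (recursive, no package internals).
oracleAncestors <- function(dag, term) {
  ed <- ontologyEdges(dag)
  seen <- character()
  walk <- function(t) {
    if (t %in% seen) return()
    seen <<- c(seen, t)
    for (p in ed$parent[ed$child == t]) walk(p)
  }
  walk(term)
  sort(seen)
}

## Independent IC: count genes whose enumerated ancestor closure hits t.
oracleIC <- function(dag, direct, term) {
  reach <- vapply(direct, function(terms) {
    anc <- unique(unlist(lapply(terms, oracleAncestors, dag = dag)))
    term %in% anc
  }, TRUE)
  n <- sum(reach)
  N <- sum(vapply(direct, length, 0L) > 0)
  -log(n / N)
}

## Independent Lin similarity via exhaustive common-ancestor enumeration.
oracleLin <- function(dag, direct, t1, t2) {
  common <- intersect(oracleAncestors(dag, t1), oracleAncestors(dag, t2))
  ics <- vapply(common, function(t) oracleIC(dag, direct, t), 0)
  ics <- ics[is.finite(ics)]
  ic1 <- oracleIC(dag, direct, t1)
  ic2 <- oracleIC(dag, direct, t2)
  if (ic1 + ic2 == 0) return(0)
  2 * max(ics) / (ic1 + ic2)
}

## Independent best-match average by exhaustive pairwise enumeration.
oracleBMA <- function(dag, direct, g1, g2) {
  t1 <- direct[[g1]]; t2 <- direct[[g2]]
  S <- outer(seq_along(t1), seq_along(t2),
             Vectorize(function(i, j) oracleLin(dag, direct, t1[i], t2[j])))
  S <- matrix(S, length(t1), length(t2))
  (mean(apply(S, 1, max)) + mean(apply(S, 2, max))) / 2
}

## Random Erdos-Renyi weighted graph.
randomGraph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- runif(nrow(idx)) < p
  weightedPPIGraph(data.frame(a = ids[idx[keep, 1]], b = ids[idx[keep, 2]],
                              confidence = runif(sum(keep))),
                   extraNodes = ids)
}

## Random DAG + annotations for property tests over the similarity engine.
randomCorpus <- function(seed, nTerms = 15, nGenes = 8) {
  set.seed(seed)
  ids <- sprintf("R:%03d", seq_len(nTerms))
  edges <- do.call(rbind, lapply(seq.int(2, nTerms), function(i) {
    k <- sample(1:2, 1)
    data.frame(child = ids[i],
               parent = sample(ids[seq_len(i - 1)], min(k, i - 1)),
               relation = "is_a", stringsAsFactors = FALSE)
  }))
  dag <- ontologyDAG(data.frame(id = ids, name = ids, namespace = "BP",
                                stringsAsFactors = FALSE), edges)
  genes <- sprintf("g%02d", seq_len(nGenes))
  direct <- lapply(setNames(genes, genes), function(g)
    sort(sample(ids[-1], sample(1:3, 1))))
  list(dag = dag, direct = direct,
       corpus = propagateAnnotations(dag, direct))
}

## Naive double-loop score oracle: for every network member, re-sum
## alpha*C + beta*F over its source-graph adjacency list with the
## membership gate, independently of scoreAll's vectorized path.
oracleScores <- function(net, graph, alpha, beta, fsim = NULL) {
  members <- c(networkSeeds(net), networkCandidates(net))
  e <- graphEdges(graph)
  netE <- networkEdges(net)
  lookupF <- function(x, y) {
    hit <- (netE$a == x & netE$b == y) | (netE$a == y & netE$b == x)
    if (any(hit)) return(netE$F[which(hit)[1]])
    if (!is.null(fsim)) fsim(x, y) else 0
  }
  out <- numeric(length(members))
  names(out) <- members
  for (i in members) {
    s <- 0
    for (r in seq_len(nrow(e))) {
      j <- if (e$a[r] == i) e$b[r] else if (e$b[r] == i) e$a[r] else next
      w <- alpha * e$confidence[r] + beta * lookupF(i, j)
      s <- s + if (j %in% members) w else -w
    }
    out[i] <- s
  }
  out
}

## Exhaustive hypergeometric upper tail by enumerating all top lists.
oracleHyperP <- function(N, K, n, k) {
  universe <- seq_len(N)
  inSet <- seq_len(K)
  combos <- utils::combn(N, n)
  hits <- apply(combos, 2, function(cl) sum(cl %in% inSet) >= k)
  mean(hits)
}

## Canonical pair key (test-local, independent of package internals).
pairKeyForTest <- function(a, b) {
  swap <- b < a
  paste(ifelse(swap, b, a), ifelse(swap, a, b), sep = "|")
}
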