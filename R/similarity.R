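## Information-content functional similarity over an ontology DAG.
## IC(t) = -ln(n(t) / N) with n(t) the number of genes whose ancestor-closed
## annotation set contains t, and N the number of annotated genes in t's
## namespace.  Term measures (Lin, normalized Resnik, relevance) are
## combined into gene-level similarity by best-match average or maximum.

## Ancestor sets (each term includes itself), computed in topological order.
computeAncestors <- function(dag) {
  ids <- dag@terms$id
  anc <- setNames(as.list(ids), ids)
  if (!nrow(dag@edges)) return(anc)
  g <- igraph::graph_from_data_frame(dag@edges[c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = ids))
  ord <- names(igraph::topo_sort(g, mode = "out"))   # children first
  parents <- split(dag@edges$parent, dag@edges$child)
  for (t in rev(ord)) {                               # parents first
    p <- parents[[t]]
    if (!is.null(p))
      anc[[t]] <- sort(unique(c(t, unlist(anc[p], use.names = FALSE))))
  }
  ## rev(ord) visits parents before children, so each child can take the
  ## union over its parents' already-final ancestor sets
  anc
}

#' Propagate annotations up the ontology
#'
#' Closes each gene's direct annotation set under ancestors (true-path
#' rule), counts per-term usage n(t), and records the number of annotated
#' genes per namespace.  Direct annotations to terms absent from the DAG
#' are dropped with a warning.
#'
#' @param dag an [OntologyDAG-class].
#' @param direct named list: gene -> character vector of directly
#'   annotated term ids (e.g. from [readGAF()]).
#' @return An [AnnotationCorpus-class].
#' @export
propagateAnnotations <- function(dag, direct) {
  stopifnot(is(dag, "OntologyDAG"), is.list(direct))
  known <- dag@terms$id
  anc <- computeAncestors(dag)
  nsOf <- setNames(dag@terms$namespace, known)
  dropped <- character()
  directClean <- list(); propagated <- list()
  for (gene in names(direct)) {
    terms <- unique(as.character(direct[[gene]]))
    bad <- setdiff(terms, known)
    if (length(bad)) {
      dropped <- c(dropped, bad)
      terms <- setdiff(terms, bad)
    }
    directClean[[gene]] <- sort(terms)
    propagated[[gene]] <-
      sort(unique(unlist(anc[terms], use.names = FALSE))) %||% character()
  }
  if (length(dropped))
    warning(sprintf(
      "dropped %d annotation(s) to terms absent from the ontology (e.g. %s)",
      length(dropped), dropped[1L]), call. = FALSE)
  counts <- table(unlist(propagated, use.names = FALSE))
  termCounts <- setNames(numeric(length(known)), known)
  termCounts[names(counts)] <- as.numeric(counts)
  nsSize <- vapply(unique(nsOf), function(ns) {
    nsTerms <- known[nsOf == ns]
    sum(vapply(propagated, function(p) any(p %in% nsTerms), TRUE))
  }, 0)
  new("AnnotationCorpus", dag = dag, direct = directClean,
      propagated = propagated, termCounts = termCounts,
      namespaceSize = nsSize, ancestors = anc)
}

termNamespaces <- function(corpus)
  setNames(corpus@dag@terms$namespace, corpus@dag@terms$id)

#' Information content of an ontology term
#'
#' IC(t) = -ln(n(t)/N) with natural logarithm.  Terms with n(t) = 0 are
#' unusable and return `NA`; similarity computations skip them.
#'
#' @param term term id (vectorized).
#' @param corpus an [AnnotationCorpus-class].
#' @return numeric vector of ICs (0 at the namespace root, `NA` where
#'   undefined).
#' @export
informationContent <- function(term, corpus) {
  ns <- termNamespaces(corpus)[term]
  n <- corpus@termCounts[term]
  N <- corpus@namespaceSize[ns]
  ic <- -log(n / N)
  ic[is.na(n) | n == 0 | is.na(N) | N == 0] <- NA_real_
  unname(ic)
}

## Maximum IC among usable terms of a namespace (normalizes resnik).
maxCorpusIC <- function(corpus, ns) {
  ids <- corpus@dag@terms$id[corpus@dag@terms$namespace == ns]
  ids <- ids[corpus@termCounts[ids] > 0]
  if (!length(ids)) return(0)
  max(informationContent(ids, corpus))
}

## MICA: usable common ancestor with maximal IC; lexicographically
## smallest id on ties (value identical by definition).
micaTerm <- function(t1, t2, corpus) {
  common <- intersect(corpus@ancestors[[t1]], corpus@ancestors[[t2]])
  common <- common[corpus@termCounts[common] > 0]
  if (!length(common)) return(NA_character_)
  ic <- informationContent(common, corpus)
  best <- common[which(ic == max(ic))]
  sort(best)[1L]
}

#' Term-level semantic similarity
#'
#' Lin: `2 IC(mica) / (IC(t1) + IC(t2))`; Resnik: `IC(mica)` min-max
#' normalized by the corpus maximum IC; rel: Lin times `1 - p(mica)`.
#' Cross-namespace pairs and pairs without a usable common ancestor give
#' 0; so does the two-roots case (IC sum of zero).
#'
#' @param t1,t2 term ids (both must be usable: annotated at least once).
#' @param corpus an [AnnotationCorpus-class].
#' @param config a [similarityConfig()] (only `termMeasure` is used here).
#' @return similarity on \[0,1\].
#' @export
termSimilarity <- function(t1, t2, corpus, config = similarityConfig()) {
  ns <- termNamespaces(corpus)
  if (is.na(ns[t1]) || is.na(ns[t2]) || ns[t1] != ns[t2]) return(0)
  ic1 <- informationContent(t1, corpus)
  ic2 <- informationContent(t2, corpus)
  if (is.na(ic1) || is.na(ic2)) return(0)
  mica <- micaTerm(t1, t2, corpus)
  if (is.na(mica)) return(0)
  icm <- informationContent(mica, corpus)
  switch(config@termMeasure,
         lin = if (ic1 + ic2 == 0) 0 else 2 * icm / (ic1 + ic2),
         resnik = {
           mx <- maxCorpusIC(corpus, ns[[t1]])
           if (mx == 0) 0 else icm / mx
         },
         rel = {
           lin <- if (ic1 + ic2 == 0) 0 else 2 * icm / (ic1 + ic2)
           p <- corpus@termCounts[[mica]] / corpus@namespaceSize[[ns[[t1]]]]
           lin * (1 - p)
         })
}

## Pairwise term-similarity matrix over usable same-namespace terms.
termSimMatrix <- function(terms, corpus, config) {
  n <- length(terms)
  m <- matrix(0, n, n, dimnames = list(terms, terms))
  if (!n) return(m)
  for (i in seq_len(n)) {
    m[i, i] <- termSimilarity(terms[i], terms[i], corpus, config)
    if (i < n) for (j in seq.int(i + 1L, n)) {
      s <- termSimilarity(terms[i], terms[j], corpus, config)
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

## Best-match average over a term-similarity submatrix.
bmaCombine <- function(S) {
  (mean(apply(S, 1L, max)) + mean(apply(S, 2L, max))) / 2
}

## Usable direct terms of a gene within one namespace.
usableDirect <- function(corpus, gene, ns) {
  t <- corpus@direct[[gene]]
  if (is.null(t)) return(character())
  nsOf <- termNamespaces(corpus)
  t <- t[!is.na(nsOf[t]) & nsOf[t] == ns]
  t[corpus@termCounts[t] > 0]
}

geneSimilarityOneNs <- function(g1, g2, corpus, config, ns) {
  t1 <- usableDirect(corpus, g1, ns)
  t2 <- usableDirect(corpus, g2, ns)
  if (!length(t1) || !length(t2)) return(NA_real_)
  S <- matrix(0, length(t1), length(t2))
  for (i in seq_along(t1)) for (j in seq_along(t2))
    S[i, j] <- termSimilarity(t1[i], t2[j], corpus, config)
  v <- if (config@geneMeasure == "bma") bmaCombine(S) else max(S)
  min(max(v, 0), 1)
}

#' Gene-level functional similarity
#'
#' Combines term similarities over the two genes' direct annotations by
#' best-match average (symmetric) or matrix maximum.  A gene with no
#' usable annotation in the active namespace yields the fallback 0.
#' Symmetric and bounded in \[0,1\] by construction.
#'
#' @param g1,g2 gene identifiers.
#' @param corpus an [AnnotationCorpus-class].
#' @param config a [similarityConfig()].
#' @return similarity on \[0,1\].
#' @export
geneSimilarity <- function(g1, g2, corpus, config = similarityConfig()) {
  nss <- if (config@namespace == "max")
    intersect(c("BP", "MF", "CC"), unique(corpus@dag@terms$namespace))
  else config@namespace
  vals <- vapply(nss, function(ns)
    geneSimilarityOneNs(g1, g2, corpus, config, ns), 0)
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else max(vals)
}

#' Gene-by-gene similarity matrix
#'
#' @param genes gene identifiers (rows = columns).
#' @param corpus an [AnnotationCorpus-class].
#' @param config a [similarityConfig()].
#' @return symmetric numeric matrix with `genes` as dimnames.
#' @export
geneSimMatrix <- function(genes, corpus, config = similarityConfig()) {
  fsim <- similarityProvider(corpus, config)
  n <- length(genes)
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    m[i, i] <- fsim(genes[i], genes[i])
    if (i < n) for (j in seq.int(i + 1L, n)) {
      s <- fsim(genes[i], genes[j])
      m[i, j] <- s; m[j, i] <- s
    }
  }
  m
}

#' Cached functional-similarity provider
#'
#' Returns a function `f(g1, g2)` computing [geneSimilarity()] with
#' memoization keyed by the unordered gene pair, and with the
#' term-similarity matrix over all directly annotated usable terms
#' precomputed once per namespace.  Used to share work across disease
#' networks, LOOCV folds and grid cells.
#'
#' @param corpus an [AnnotationCorpus-class].
#' @param config a [similarityConfig()].
#' @param fallback value returned when either gene lacks usable
#'   annotation (default 0).
#' @return a memoized function of two gene identifiers.
#' @export
similarityProvider <- function(corpus, config = similarityConfig(),
                               fallback = 0) {
  nss <- if (config@namespace == "max")
    intersect(c("BP", "MF", "CC"), unique(corpus@dag@terms$namespace))
  else config@namespace
  ## per-namespace: usable direct term universe and its similarity matrix
  pre <- list()
  for (ns in nss) {
    used <- sort(unique(unlist(corpus@direct, use.names = FALSE)))
    nsOf <- termNamespaces(corpus)
    used <- used[!is.na(nsOf[used]) & nsOf[used] == ns]
    used <- used[corpus@termCounts[used] > 0]
    pre[[ns]] <- list(terms = used,
                      S = termSimMatrix(used, corpus, config))
  }
  geneTerms <- lapply(setNames(nss, nss), function(ns)
    lapply(corpus@direct, function(t) intersect(t, pre[[ns]]$terms)))
  cache <- new.env(parent = emptyenv())
  function(g1, g2) {
    key <- pairKey(g1, g2)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    vals <- numeric(0)
    for (ns in nss) {
      t1 <- geneTerms[[ns]][[g1]]
      t2 <- geneTerms[[ns]][[g2]]
      if (is.null(t1) || is.null(t2) || !length(t1) || !length(t2)) next
      S <- pre[[ns]]$S[t1, t2, drop = FALSE]
      v <- if (config@geneMeasure == "bma") bmaCombine(S) else max(S)
      vals <- c(vals, min(max(v, 0), 1))
    }
    out <- if (length(vals)) max(vals) else fallback
    cache[[key]] <- out
    out
  }
}
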