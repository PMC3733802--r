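#' @import methods
#' @importFrom stats rbeta phyper p.adjust setNames
#' @importFrom utils write.table head
NULL

## ---------------------------------------------------------------------------
## WeightedPPIGraph
## ---------------------------------------------------------------------------

#' Weighted protein-protein interaction graph
#'
#' Undirected interaction graph with one confidence value per edge.
#' Confidences live on \[0, 1\] (STRING-style 0-999 combined scores are
#' rescaled on ingestion, see [readPPITable()]).  Edges are stored once in
#' canonical order (first endpoint lexicographically smaller), so a graph
#' built from any permutation of the same rows is identical.
#'
#' @slot nodes character vector of protein identifiers, sorted.
#' @slot edges data.frame with columns `a`, `b`, `confidence`.
#' @export
setClass("WeightedPPIGraph",
         representation(nodes = "character", edges = "data.frame"))

setValidity("WeightedPPIGraph", function(object) {
  e <- object@edges
  if (!identical(colnames(e), c("a", "b", "confidence")))
    return("edges must have columns a, b, confidence")
  if (nrow(e)) {
    if (any(e$a >= e$b)) return("edges must be canonical (a < b, no self-loops)")
    if (anyDuplicated(paste(e$a, e$b, sep = "\r"))) return("duplicate edges")
    if (any(e$confidence < 0 | e$confidence > 1))
      return("confidence values must lie in [0, 1]")
    if (!all(c(e$a, e$b) %in% object@nodes))
      return("edge endpoints missing from node set")
  }
  if (is.unsorted(object@nodes) || anyDuplicated(object@nodes))
    return("nodes must be sorted and unique")
  TRUE
})

#' Construct a WeightedPPIGraph from an edge table
#'
#' Duplicate unordered pairs are collapsed keeping the maximum confidence;
#' self-loops are dropped with a warning.
#'
#' @param edges data.frame with columns `a`, `b`, `confidence` (on \[0,1\]).
#' @param extraNodes identifiers to include as isolated nodes.
#' @return A [WeightedPPIGraph-class] object.
#' @export
weightedPPIGraph <- function(edges, extraNodes = character()) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(ncol(edges) >= 3)
  colnames(edges)[1:3] <- c("a", "b", "confidence")
  edges$a <- as.character(edges$a)
  edges$b <- as.character(edges$b)
  self <- edges$a == edges$b
  if (any(self)) {
    warning(sprintf("dropping %d self-interaction(s) (e.g. %s)",
                    sum(self), edges$a[which(self)[1L]]), call. = FALSE)
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges)) {
    cp <- canonicalPairs(edges$a, edges$b)
    edges$a <- cp$a; edges$b <- cp$b
    key <- paste(edges$a, edges$b, sep = "\r")
    conf <- tapply(edges$confidence, key, max)
    keep <- !duplicated(key)
    edges <- edges[keep, c("a", "b", "confidence")]
    edges$confidence <- as.numeric(conf[paste(edges$a, edges$b, sep = "\r")])
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = character(), b = character(),
                        confidence = numeric(), stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(edges$a, edges$b, as.character(extraNodes))))
  new("WeightedPPIGraph", nodes = nodes, edges = edges)
}

#' @describeIn weightedPPIGraph node identifiers of a graph.
#' @param x a `WeightedPPIGraph`.
#' @export
graphNodes <- function(x) x@nodes

#' @describeIn weightedPPIGraph edge table (`a`, `b`, `confidence`).
#' @export
graphEdges <- function(x) x@edges

setMethod("show", "WeightedPPIGraph", function(object) {
  cat(sprintf("WeightedPPIGraph: %d nodes, %d edges\n",
              length(object@nodes), nrow(object@edges)))
  if (nrow(object@edges))
    cat(sprintf("  confidence range: [%.3f, %.3f]\n",
                min(object@edges$confidence), max(object@edges$confidence)))
})

## Adjacency as a named list of data.frames (j, confidence).
ppiAdjacency <- function(graph, nodes = NULL) {
  e <- graph@edges
  long <- data.frame(i = c(e$a, e$b), j = c(e$b, e$a),
                     confidence = c(e$confidence, e$confidence),
                     stringsAsFactors = FALSE)
  if (!is.null(nodes)) long <- long[long$i %in% nodes, , drop = FALSE]
  split(long[c("j", "confidence")], factor(long$i, levels = unique(long$i)))
}

## Neighbor id sets for a vector of nodes.
ppiNeighbors <- function(graph, nodes) {
  e <- graph@edges
  hitA <- e$a %in% nodes
  hitB <- e$b %in% nodes
  sort(unique(c(e$b[hitA], e$a[hitB])))
}

## ---------------------------------------------------------------------------
## SeedSet
## ---------------------------------------------------------------------------

#' Seed protein set
#'
#' Ordered, duplicate-free list of known disease proteins anchoring a
#' disease-specific network, optionally with a symbol-to-accession map.
#'
#' @slot label disease label.
#' @slot members character vector of identifiers (order preserved).
#' @slot accessions named character vector mapping member to accession.
#' @export
setClass("SeedSet",
         representation(label = "character", members = "character",
                        accessions = "character"))

setValidity("SeedSet", function(object) {
  if (length(object@members) == 0L) return("seed set must be non-empty")
  if (anyDuplicated(object@members)) return("seed members must be unique")
  if (length(object@accessions) &&
      !all(names(object@accessions) %in% object@members))
    return("accessions must be named by seed members")
  TRUE
})

#' @describeIn seedSet seed member identifiers.
#' @export
seedMembers <- function(x) x@members

#' @describeIn seedSet disease label.
#' @export
seedLabel <- function(x) x@label

#' Construct a SeedSet
#'
#' @param members character vector of identifiers.
#' @param label disease label.
#' @param accessions optional named character vector (names in `members`).
#' @export
seedSet <- function(members, label = "disease", accessions = character()) {
  checkProteinIds(members, "seed identifier")
  new("SeedSet", label = label, members = as.character(members),
      accessions = accessions)
}

setMethod("show", "SeedSet", function(object) {
  cat(sprintf("SeedSet '%s': %d members\n", object@label,
              length(object@members)))
  cat("  ", paste(head(object@members, 8L), collapse = ", "),
      if (length(object@members) > 8L) ", ..." else "", "\n", sep = "")
})

## ---------------------------------------------------------------------------
## OntologyDAG
## ---------------------------------------------------------------------------

#' Ontology DAG
#'
#' Directed acyclic graph of ontology terms; edges point child -> parent
#' along `is_a` (and optionally `part_of`) relations.  Namespaces use the
#' short codes `BP`, `MF`, `CC`.
#'
#' @slot terms data.frame with columns `id`, `name`, `namespace`.
#' @slot edges data.frame with columns `child`, `parent`, `relation`.
#' @slot roots character vector of terms with no parent.
#' @export
setClass("OntologyDAG",
         representation(terms = "data.frame", edges = "data.frame",
                        roots = "character"))

setValidity("OntologyDAG", function(object) {
  if (!all(c("id", "name", "namespace") %in% colnames(object@terms)))
    return("terms must have id, name, namespace")
  if (anyDuplicated(object@terms$id)) return("duplicate term ids")
  if (nrow(object@edges) &&
      !all(c(object@edges$child, object@edges$parent) %in% object@terms$id))
    return("edge endpoints missing from term table")
  TRUE
})

#' Construct an OntologyDAG, checking acyclicity
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `relation`.
#' @return An [OntologyDAG-class]; errors listing one cycle if the edge set
#'   is not acyclic.
#' @export
ontologyDAG <- function(terms, edges) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!nrow(edges))
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  cyc <- findCycle(terms$id, edges)
  if (!is.null(cyc))
    gbaFormatError("ontology contains a cycle: %s",
                   paste(c(cyc, cyc[1L]), collapse = " -> "))
  roots <- setdiff(terms$id, edges$child)
  new("OntologyDAG", terms = terms, edges = edges, roots = sort(roots))
}

## Kahn trimming; returns NULL if acyclic, else one cycle as a term vector.
findCycle <- function(ids, edges) {
  if (!nrow(edges)) return(NULL)
  g <- igraph::graph_from_data_frame(edges[c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = ids))
  if (igraph::is_dag(g)) return(NULL)
  ## locate a cycle: walk parent links from any vertex on a strongly
  ## connected component of size > 1 (or a self-loop)
  comp <- igraph::components(g, mode = "strong")
  cid <- which(comp$csize > 1L)[1L]
  members <- ids[comp$membership == cid]
  sub <- edges[edges$child %in% members & edges$parent %in% members, ]
  path <- members[1L]
  repeat {
    nxt <- sub$parent[sub$child == path[length(path)]][1L]
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(path[i:length(path)])
    }
    path <- c(path, nxt)
  }
}

#' @describeIn ontologyDAG term table of a DAG.
#' @param x an `OntologyDAG`.
#' @export
ontologyTerms <- function(x) x@terms

#' @describeIn ontologyDAG child-to-parent edge table.
#' @export
ontologyEdges <- function(x) x@edges

#' @describeIn ontologyDAG root terms (one or more per namespace).
#' @export
ontologyRoots <- function(x) x@roots

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d edges, %d root(s)\n",
              nrow(object@terms), nrow(object@edges), length(object@roots)))
  ns <- table(object@terms$namespace)
  cat("  namespaces:", paste(sprintf("%s=%d", names(ns), ns), collapse = ", "),
      "\n")
})

## ---------------------------------------------------------------------------
## AnnotationCorpus
## ---------------------------------------------------------------------------

#' Annotation corpus
#'
#' Ontology DAG together with direct and ancestor-propagated gene
#' annotations, per-term usage counts n(t), and the number of annotated
#' genes per namespace — everything the information-content machinery needs.
#'
#' @slot dag the [OntologyDAG-class].
#' @slot direct named list: gene -> character vector of directly annotated terms.
#' @slot propagated named list: gene -> ancestor-closed term set.
#' @slot termCounts named numeric: term -> number of genes reaching it.
#' @slot namespaceSize named numeric: namespace -> number of annotated genes.
#' @slot ancestors named list: term -> ancestor set (including itself).
#' @export
setClass("AnnotationCorpus",
         representation(dag = "OntologyDAG", direct = "list",
                        propagated = "list", termCounts = "numeric",
                        namespaceSize = "numeric", ancestors = "list"))

setValidity("AnnotationCorpus", function(object) {
  g <- names(object@direct)
  if (!identical(g, names(object@propagated)))
    return("direct and propagated annotations must cover the same genes")
  for (gene in g)
    if (!all(object@direct[[gene]] %in% object@propagated[[gene]]))
      return(sprintf("propagated set of '%s' does not contain its direct set",
                     gene))
  TRUE
})

#' @describeIn propagateAnnotations genes present in the corpus.
#' @export
annotatedGenes <- function(corpus) names(corpus@direct)

#' @describeIn propagateAnnotations direct term annotations of one gene.
#' @param gene gene identifier.
#' @export
directAnnotations <- function(corpus, gene) corpus@direct[[gene]] %||% character()

#' @describeIn propagateAnnotations ancestor-closed annotations of one gene.
#' @export
propagatedAnnotations <- function(corpus, gene)
  corpus@propagated[[gene]] %||% character()

setMethod("show", "AnnotationCorpus", function(object) {
  cat(sprintf("AnnotationCorpus: %d genes, %d used terms\n",
              length(object@direct), sum(object@termCounts > 0)))
  cat("  annotated genes per namespace:",
      paste(sprintf("%s=%d", names(object@namespaceSize),
                    object@namespaceSize), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Similarity / edge-weight configuration
## ---------------------------------------------------------------------------

#' Functional-similarity configuration
#'
#' @param namespace ontology namespace used for similarity: `"BP"`, `"MF"`,
#'   `"CC"`, or `"max"` (maximum over namespaces).
#' @param termMeasure term-level measure: `"lin"`, `"resnik"` (min-max
#'   normalized by the corpus maximum IC), or `"rel"`.
#' @param geneMeasure combination rule: `"bma"` (best-match average) or
#'   `"max"`.
#' @return A `SimilarityConfig` object.  Information content always uses
#'   the natural logarithm.
#' @export
similarityConfig <- function(namespace = c("BP", "MF", "CC", "max"),
                             termMeasure = c("lin", "resnik", "rel"),
                             geneMeasure = c("bma", "max")) {
  new("SimilarityConfig", namespace = match.arg(namespace),
      termMeasure = match.arg(termMeasure),
      geneMeasure = match.arg(geneMeasure))
}

#' @rdname similarityConfig
#' @export
setClass("SimilarityConfig",
         representation(namespace = "character", termMeasure = "character",
                        geneMeasure = "character"))

#' Edge-weight configuration for disease networks
#'
#' @param sim a [similarityConfig()].
#' @param fallback functional-similarity value used when either endpoint
#'   has no usable annotation (must lie in \[0,1\]).
#' @param policy `"induced"` keeps every source-graph edge among
#'   seeds+candidates (candidate-candidate edges included);
#'   `"seed_incident"` keeps only edges touching a seed.
#' @export
edgeWeightConfig <- function(sim = similarityConfig(), fallback = 0,
                             policy = c("induced", "seed_incident")) {
  policy <- match.arg(policy)
  stopifnot(fallback >= 0, fallback <= 1)
  new("EdgeWeightConfig", sim = sim, fallback = fallback, policy = policy)
}

#' @rdname edgeWeightConfig
#' @export
setClass("EdgeWeightConfig",
         representation(sim = "SimilarityConfig", fallback = "numeric",
                        policy = "character"))

## ---------------------------------------------------------------------------
## DiseaseNetwork
## ---------------------------------------------------------------------------

#' Disease-specific PPI network
#'
#' Seeds plus their direct interaction neighbors (candidates), with two
#' weights per edge: interaction confidence `C` and functional similarity
#' `F`, both on \[0,1\].
#'
#' @slot label disease label.
#' @slot seeds seed proteins present in the source graph (sorted).
#' @slot candidates direct neighbors of seeds, excluding seeds (sorted).
#' @slot edges data.frame with columns `a`, `b`, `C`, `F`.
#' @slot policy edge-inclusion policy used ("induced" or "seed_incident").
#' @export
setClass("DiseaseNetwork",
         representation(label = "character", seeds = "character",
                        candidates = "character", edges = "data.frame",
                        policy = "character"))

setValidity("DiseaseNetwork", function(object) {
  if (length(intersect(object@seeds, object@candidates)))
    return("seeds and candidates must be disjoint")
  e <- object@edges
  if (!identical(colnames(e), c("a", "b", "C", "F")))
    return("edges must have columns a, b, C, F")
  if (nrow(e)) {
    if (any(e$C < 0 | e$C > 1) || any(e$F < 0 | e$F > 1))
      return("edge weights C and F must lie in [0, 1]")
    members <- c(object@seeds, object@candidates)
    if (!all(c(e$a, e$b) %in% members))
      return("edge endpoints outside seeds + candidates")
  }
  TRUE
})

#' @describeIn buildDiseaseNetwork seed nodes of a disease network.
#' @export
networkSeeds <- function(net) net@seeds

#' @describeIn buildDiseaseNetwork candidate nodes of a disease network.
#' @export
networkCandidates <- function(net) net@candidates

#' @describeIn buildDiseaseNetwork edge table with both weights (`a`, `b`,
#'   `C`, `F`).
#' @export
networkEdges <- function(net) net@edges

#' @describeIn buildDiseaseNetwork membership indicator: named 0/1 vector
#'   over `ids` (1 when the protein belongs to the disease network).
#' @param ids protein identifiers to test.
#' @export
networkMembership <- function(net, ids)
  setNames(as.integer(ids %in% c(net@seeds, net@candidates)), ids)

setMethod("show", "DiseaseNetwork", function(object) {
  cat(sprintf("DiseaseNetwork '%s' (%s policy)\n", object@label,
              object@policy))
  cat(sprintf("  %d seeds, %d candidates, %d edges\n",
              length(object@seeds), length(object@candidates),
              nrow(object@edges)))
})

## ---------------------------------------------------------------------------
## ScoreParams / ScoreTable
## ---------------------------------------------------------------------------

#' Disease-relevance score parameters
#'
#' `alpha` weights interaction confidence, `beta` functional similarity.
#' The default `additive_penalized` formula is
#' \deqn{S(i) = \sum_{j \in N(i)} (\alpha C_{ij} + \beta F_{ij}) I(j) -
#'       \sum_{j \in N(i)} (\alpha C_{ij} + \beta F_{ij}) (1 - I(j))}
#' where `N(i)` are the neighbors of `i` in the full source graph and
#' `I(j)` indicates membership in the disease network.  A custom formula
#' can be plugged in: `plugin(neighborData, alpha, beta)` receives a
#' data.frame with columns `j`, `C`, `F`, `I` and must return one number.
#'
#' @param alpha positive confidence weight.
#' @param beta positive functional-similarity weight.
#' @param formula `"additive_penalized"` (default) or `"plugin"`.
#' @param plugin function used when `formula = "plugin"`.
#' @export
scoreParams <- function(alpha = 1, beta = 1,
                        formula = c("additive_penalized", "plugin"),
                        plugin = NULL) {
  formula <- match.arg(formula)
  stopifnot(is.numeric(alpha), is.numeric(beta), alpha > 0, beta > 0)
  if (formula == "plugin" && !is.function(plugin))
    gbaUsageError("formula = 'plugin' requires a plugin function")
  new("ScoreParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      formula = formula, plugin = if (is.null(plugin)) list() else list(plugin))
}

#' @rdname scoreParams
#' @export
setClass("ScoreParams",
         representation(alpha = "numeric", beta = "numeric",
                        formula = "character", plugin = "list"))

#' Score table
#'
#' Per-protein disease relevance scores.  Seeds are scored but only
#' candidates receive ranks (1 = best; ties broken by identifier).
#'
#' @slot table data.frame with columns `protein`, `isSeed`, `score`, `rank`
#'   (`NA` for seeds).
#' @slot alpha,beta parameters used.
#' @slot accessions named character vector (may be empty).
#' @slot fingerprint short text describing the scored network.
#' @export
setClass("ScoreTable",
         representation(table = "data.frame", alpha = "numeric",
                        beta = "numeric", accessions = "character",
                        fingerprint = "character"))

setValidity("ScoreTable", function(object) {
  tb <- object@table
  if (!all(c("protein", "isSeed", "score", "rank") %in% colnames(tb)))
    return("table must have protein, isSeed, score, rank")
  r <- tb$rank[!tb$isSeed]
  r <- r[!is.na(r)]
  if (length(r) && !setequal(r, seq_along(r)))
    return("candidate ranks must be a permutation of 1..n")
  TRUE
})

#' @describeIn scoreAll the underlying data.frame of a score table.
#' @export
scoreTable <- function(x) x@table

#' @describeIn scoreAll candidate rows of a score table in rank order.
#' @export
rankedCandidates <- function(x) {
  tb <- x@table[!x@table$isSeed & !is.na(x@table$rank), , drop = FALSE]
  tb[order(tb$rank), , drop = FALSE]
}

setMethod("show", "ScoreTable", function(object) {
  tb <- object@table
  cat(sprintf("ScoreTable (alpha=%g, beta=%g): %d seeds, %d candidates\n",
              object@alpha, object@beta, sum(tb$isSeed), sum(!tb$isSeed)))
  top <- head(rankedCandidates(object), 5L)
  if (nrow(top)) {
    cat("  top candidates:\n")
    for (i in seq_len(nrow(top)))
      cat(sprintf("    %2d. %s  (S = %.4g)\n", top$rank[i], top$protein[i],
                  top$score[i]))
  }
})

## ---------------------------------------------------------------------------
## RocCurve / GridResult
## ---------------------------------------------------------------------------

#' ROC curve over LOOCV folds
#'
#' @slot points data.frame with columns `fpr` (1 - specificity) and `tpr`
#'   (sensitivity), sorted and spanning (0,0) to (1,1).
#' @slot auc trapezoidal area under the curve.
#' @slot nFolds number of folds the curve summarizes.
#' @export
setClass("RocCurve",
         representation(points = "data.frame", auc = "numeric",
                        nFolds = "integer"))

setValidity("RocCurve", function(object) {
  p <- object@points
  if (!all(c("fpr", "tpr") %in% colnames(p))) return("points need fpr, tpr")
  if (nrow(p)) {
    if (is.unsorted(p$fpr) || is.unsorted(p$tpr))
      return("ROC points must be non-decreasing in both coordinates")
    if (abs(p$fpr[1L]) > 1e-12 || abs(p$tpr[1L]) > 1e-12 ||
        abs(p$fpr[nrow(p)] - 1) > 1e-12 || abs(p$tpr[nrow(p)] - 1) > 1e-12)
      return("ROC curve must span (0,0) to (1,1)")
  }
  if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
  TRUE
})

#' @describeIn rocFromFolds area under a ROC curve.
#' @export
rocAUC <- function(x) x@auc

#' @describeIn rocFromFolds points of a ROC curve (`fpr`, `tpr`).
#' @export
rocPoints <- function(x) x@points

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: AUC = %.4f over %d folds (%d points)\n",
              object@auc, object@nFolds, nrow(object@points)))
})

#' (alpha, beta) grid-search result
#'
#' @slot grid data.frame with columns `alpha`, `beta`, `auc` covering the
#'   full Cartesian product.
#' @slot bestAlpha,bestBeta selected constants (maximum AUC; ties broken by
#'   smallest alpha then smallest beta).
#' @slot objective AUC at the selected cell.
#' @export
setClass("GridResult",
         representation(grid = "data.frame", bestAlpha = "numeric",
                        bestBeta = "numeric", objective = "numeric"))

#' @describeIn gridSearch the full grid as a data.frame.
#' @export
gridTable <- function(x) x@grid

#' @describeIn gridSearch selected constants as c(alpha, beta).
#' @export
gridBest <- function(x) c(alpha = x@bestAlpha, beta = x@bestBeta)

#' @describeIn gridSearch alpha-by-beta AUC matrix.
#' @export
gridMatrix <- function(x) {
  a <- sort(unique(x@grid$alpha)); b <- sort(unique(x@grid$beta))
  m <- matrix(NA_real_, length(a), length(b),
              dimnames = list(alpha = as.character(a),
                              beta = as.character(b)))
  m[cbind(match(x@grid$alpha, a), match(x@grid$beta, b))] <- x@grid$auc
  m
}

setMethod("show", "GridResult", function(object) {
  cat(sprintf("GridResult: %d combinations; best (alpha=%g, beta=%g), AUC = %.4f\n",
              nrow(object@grid), object@bestAlpha, object@bestBeta,
              object@objective))
})

## ---------------------------------------------------------------------------
## GeneSetCollection (for enrichment)
## ---------------------------------------------------------------------------

#' Named gene sets over a universe
#'
#' @param sets named list of character vectors.
#' @param universe universe of identifiers; defaults to the union of the
#'   sets.  Every set must be a subset of the universe.
#' @export
geneSetCollection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  sets <- lapply(sets, function(s) sort(unique(as.character(s))))
  if (is.null(universe)) universe <- sort(unique(unlist(sets)))
  universe <- sort(unique(as.character(universe)))
  new("GeneSetCollection", sets = sets, universe = universe)
}

#' @rdname geneSetCollection
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", universe = "character"))

setValidity("GeneSetCollection", function(object) {
  for (nm in names(object@sets))
    if (!all(object@sets[[nm]] %in% object@universe))
      return(sprintf("set '%s' is not a subset of the universe", nm))
  TRUE
})

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d sets over a universe of %d genes\n",
              length(object@sets), length(object@universe)))
})

## ---------------------------------------------------------------------------
## Synthetic-study containers
## ---------------------------------------------------------------------------

#' Synthetic-study parameters
#'
#' Defaults describe the reference simulation: 200 genes carrying a planted
#' 25-gene disease module, 10 of which are designated seeds; module pairs
#' interact with probability 0.30 and confidences drawn from Beta(8,2),
#' background pairs with probability 0.02 and Beta(2,5) confidences; a
#' 60-term single-namespace ontology whose dedicated module subtree (8
#' terms) annotates module genes, giving them high pairwise functional
#' similarity.
#'
#' @param nGenes total number of genes.
#' @param moduleSize size of the planted disease module.
#' @param nSeeds number of module genes designated as seeds.
#' @param pIn,pOut within-module / background edge probabilities.
#' @param confIn,confOut Beta shape pairs for edge confidences.
#' @param nTerms,maxDepth ontology size and depth cap.
#' @param moduleTermCount size of the dedicated module subtree (>= 5).
#' @param moduleTermsPerGene,backgroundTermsPerGene inclusive integer
#'   ranges (length-2) of direct annotations per gene.
#' @param sharedAnnotations if `FALSE`, module genes are annotated like
#'   background genes (annotation channel of the planted signal disabled).
#' @export
simParams <- function(nGenes = 200L, moduleSize = 25L, nSeeds = 10L,
                      pIn = 0.30, pOut = 0.02,
                      confIn = c(8, 2), confOut = c(2, 5),
                      nTerms = 60L, maxDepth = 5L, moduleTermCount = 8L,
                      moduleTermsPerGene = c(2L, 4L),
                      backgroundTermsPerGene = c(1L, 3L),
                      sharedAnnotations = TRUE) {
  new("SimParams", nGenes = as.integer(nGenes),
      moduleSize = as.integer(moduleSize), nSeeds = as.integer(nSeeds),
      pIn = pIn, pOut = pOut, confIn = confIn, confOut = confOut,
      nTerms = as.integer(nTerms), maxDepth = as.integer(maxDepth),
      moduleTermCount = as.integer(moduleTermCount),
      moduleTermsPerGene = as.integer(moduleTermsPerGene),
      backgroundTermsPerGene = as.integer(backgroundTermsPerGene),
      sharedAnnotations = sharedAnnotations)
}

#' @rdname simParams
#' @export
setClass("SimParams",
         representation(nGenes = "integer", moduleSize = "integer",
                        nSeeds = "integer", pIn = "numeric", pOut = "numeric",
                        confIn = "numeric", confOut = "numeric",
                        nTerms = "integer", maxDepth = "integer",
                        moduleTermCount = "integer",
                        moduleTermsPerGene = "integer",
                        backgroundTermsPerGene = "integer",
                        sharedAnnotations = "logical"))

setValidity("SimParams", function(object) {
  if (!(object@pOut >= 0 && object@pOut <= object@pIn && object@pIn <= 1 &&
        object@pIn > 0))
    return("need 0 <= pOut <= pIn <= 1 with pIn > 0")
  if (!(object@nSeeds < object@moduleSize &&
        object@moduleSize < object@nGenes))
    return("need nSeeds < moduleSize < nGenes")
  if (object@nTerms < 3L) return("need at least 3 ontology terms")
  if (object@moduleTermCount < 5L) return("module subtree needs >= 5 terms")
  if (object@moduleTermCount + 1L >= object@nTerms)
    return("nTerms too small for the module subtree")
  TRUE
})

#' Synthetic study bundle
#'
#' @slot graph the simulated [WeightedPPIGraph-class].
#' @slot dag the simulated [OntologyDAG-class].
#' @slot annotations named list gene -> direct term annotations.
#' @slot moduleTerms terms of the dedicated module subtree.
#' @slot truth planted disease-module genes (ground truth).
#' @slot seeds [SeedSet-class], a subset of `truth`.
#' @slot params the [simParams()] used.
#' @slot seed generator seed.
#' @export
setClass("SyntheticStudy",
         representation(graph = "WeightedPPIGraph", dag = "OntologyDAG",
                        annotations = "list", moduleTerms = "character",
                        truth = "character", seeds = "SeedSet",
                        params = "SimParams", seed = "integer"))

setValidity("SyntheticStudy", function(object) {
  if (!all(object@seeds@members %in% object@truth))
    return("seeds must be a subset of the planted module")
  if (!all(object@truth %in% object@graph@nodes))
    return("planted module must be inside the graph")
  TRUE
})

setMethod("show", "SyntheticStudy", function(object) {
  cat(sprintf("SyntheticStudy (seed %d): %d genes, module %d, %d seeds\n",
              object@seed, object@params@nGenes, length(object@truth),
              length(object@seeds@members)))
  cat(sprintf("  graph: %d edges; ontology: %d terms\n",
              nrow(object@graph@edges), nrow(object@dag@terms)))
})
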