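## Synthetic-study generator.  Emulates the method's assumed statistical
## structure (guilt by association): a planted disease module whose genes
## preferentially interact with high-confidence edges and share a
## dedicated subtree of ontology annotations.  One integer seed determines
## every byte of the generated fixtures.

synGeneIds <- function(n) sprintf("G%04d", seq_len(n))
synTermIds <- function(n) sprintf("SYN:%06d", seq_len(n))

#' Simulate a rooted ontology DAG
#'
#' Terms are attached one by one to 1-2 existing parents subject to the
#' depth cap, so the result is acyclic by construction.  The first
#' `moduleTermCount` non-root terms form a dedicated module subtree
#' hanging off the root; background terms attach only to the root or to
#' other background terms, keeping the subtree exclusive to the planted
#' module's annotations.
#'
#' @param params a [simParams()].
#' @param seed integer generator seed (or `NULL` to use the current RNG
#'   state).
#' @return list with elements `dag` ([OntologyDAG-class]) and
#'   `moduleTerms`.
#' @export
simulateOntology <- function(params = simParams(), seed = NULL) {
  withSeed(seed, {
    n <- params@nTerms
    ids <- synTermIds(n)
    root <- ids[1L]
    moduleTerms <- ids[seq.int(2L, params@moduleTermCount + 1L)]
    depth <- setNames(integer(n), ids)
    edges <- list()
    pickParents <- function(pool) {
      pool <- pool[depth[pool] < params@maxDepth - 1L]
      if (!length(pool)) return(character())
      k <- min(length(pool), sample.int(2L, 1L))
      if (length(pool) == 1L) pool else sample(pool, k)
    }
    ## module subtree: anchor is a child of the root
    depth[moduleTerms[1L]] <- 1L
    edges[[moduleTerms[1L]]] <- data.frame(
      child = moduleTerms[1L], parent = root, relation = "is_a",
      stringsAsFactors = FALSE)
    for (t in moduleTerms[-1L]) {
      pool <- moduleTerms[seq_len(match(t, moduleTerms) - 1L)]
      par <- pickParents(pool)
      if (!length(par)) par <- moduleTerms[1L]
      depth[t] <- max(depth[par]) + 1L
      edges[[t]] <- data.frame(child = t, parent = par,
                               relation = "is_a", stringsAsFactors = FALSE)
    }
    ## background terms: root plus previously placed background terms
    bgTerms <- setdiff(ids, c(root, moduleTerms))
    placed <- root
    for (t in bgTerms) {
      par <- pickParents(placed)
      if (!length(par)) par <- root
      depth[t] <- max(depth[par]) + 1L
      edges[[t]] <- data.frame(child = t, parent = par,
                               relation = "is_a", stringsAsFactors = FALSE)
      placed <- c(placed, t)
    }
    terms <- data.frame(id = ids, name = sprintf("synthetic term %d",
                                                 seq_len(n)),
                        namespace = "BP", stringsAsFactors = FALSE)
    list(dag = ontologyDAG(terms, do.call(rbind, edges)),
         moduleTerms = moduleTerms)
  })
}

#' Simulate direct gene annotations
#'
#' Module genes draw 2-4 terms from the dedicated module subtree (high
#' pairwise functional similarity); background genes draw 1-3 terms
#' uniformly from the remaining non-root terms.  With
#' `sharedAnnotations = FALSE` every gene is annotated like background,
#' removing the planted annotation signal.
#'
#' @param dag an [OntologyDAG-class] from [simulateOntology()].
#' @param moduleTerms the dedicated module subtree.
#' @param genes all gene identifiers.
#' @param truth planted-module gene identifiers.
#' @param params a [simParams()].
#' @param seed integer generator seed (or `NULL`).
#' @return named list gene -> character vector of direct term ids.
#' @export
simulateAnnotations <- function(dag, moduleTerms, genes, truth,
                                params = simParams(), seed = NULL) {
  withSeed(seed, {
    ids <- ontologyTerms(dag)$id
    root <- ontologyRoots(dag)
    bgTerms <- setdiff(ids, c(root, moduleTerms))
    mRange <- params@moduleTermsPerGene
    bRange <- params@backgroundTermsPerGene
    ann <- lapply(setNames(genes, genes), function(g) {
      if (params@sharedAnnotations && g %in% truth) {
        k <- sample(seq.int(mRange[1L], mRange[2L]), 1L)
        sort(sample(moduleTerms, min(k, length(moduleTerms))))
      } else {
        k <- sample(seq.int(bRange[1L], bRange[2L]), 1L)
        sort(sample(bgTerms, min(k, length(bgTerms))))
      }
    })
    ann
  })
}

#' Simulate a weighted PPI graph with a planted module
#'
#' Every within-module gene pair becomes an edge with probability `pIn`
#' and confidence drawn from `Beta(confIn)`, every other pair with
#' probability `pOut` and `Beta(confOut)` confidence.
#'
#' @param params a [simParams()].
#' @param genes all gene identifiers.
#' @param truth planted-module gene identifiers.
#' @param seed integer generator seed (or `NULL`).
#' @return A [WeightedPPIGraph-class] containing all genes (isolated ones
#'   included).
#' @export
simulatePPI <- function(params = simParams(), genes, truth, seed = NULL) {
  withSeed(seed, {
    n <- length(genes)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    a <- genes[idx[, 1L]]
    b <- genes[idx[, 2L]]
    within <- (a %in% truth) & (b %in% truth)
    p <- ifelse(within, params@pIn, params@pOut)
    present <- stats::runif(length(p)) < p
    conf <- numeric(sum(present))
    w <- within[present]
    conf[w] <- rbeta(sum(w), params@confIn[1L], params@confIn[2L])
    conf[!w] <- rbeta(sum(!w), params@confOut[1L], params@confOut[2L])
    conf <- pmin(pmax(conf, 0), 1)
    weightedPPIGraph(data.frame(a = a[present], b = b[present],
                                confidence = conf,
                                stringsAsFactors = FALSE),
                     extraNodes = genes)
  })
}

#' Simulate a complete synthetic study
#'
#' Composes ontology, annotations and PPI generators, plants the disease
#' module, and designates a uniformly drawn subset of module genes as
#' seeds.  Regenerating with the same seed and parameters is
#' bit-identical.
#'
#' @param params a [simParams()].
#' @param seed integer generator seed.
#' @return A [SyntheticStudy-class].
#' @examples
#' study <- simulateStudy(seed = 42)
#' study
#' @export
simulateStudy <- function(params = simParams(), seed = 1L) {
  seed <- as.integer(seed)
  withSeed(seed, {
    genes <- synGeneIds(params@nGenes)
    truth <- sort(sample(genes, params@moduleSize))
    onto <- simulateOntology(params, seed = NULL)
    ann <- simulateAnnotations(onto$dag, onto$moduleTerms, genes, truth,
                               params, seed = NULL)
    graph <- simulatePPI(params, genes, truth, seed = NULL)
    seeds <- seedSet(sort(sample(truth, params@nSeeds)),
                     label = "synthetic")
    new("SyntheticStudy", graph = graph, dag = onto$dag,
        annotations = ann, moduleTerms = onto$moduleTerms, truth = truth,
        seeds = seeds, params = params, seed = seed)
  })
}

#' Null-study parameters
#'
#' Configuration with the planted guilt-by-association signal removed:
#' equal edge probabilities inside and outside the module, one confidence
#' distribution for all edges, and no shared module annotations.  The
#' common edge probability is kept high (0.30) so that held-out seeds are
#' almost always recoverable candidates — under a sparse null most folds
#' would hit the sentinel worst rank and the AUC would measure seed
#' connectivity rather than ranking behavior.
#'
#' @param pEdge common edge probability.
#' @param conf common Beta shape pair for confidences.
#' @param ... further arguments passed to [simParams()].
#' @return A [simParams()] object describing the null.
#' @export
nullStudyParams <- function(pEdge = 0.30, conf = c(2, 5), ...) {
  simParams(pIn = pEdge, pOut = pEdge, confIn = conf, confOut = conf,
            sharedAnnotations = FALSE, ...)
}

#' Annotation corpus of a synthetic study
#'
#' @param study a [SyntheticStudy-class].
#' @return An [AnnotationCorpus-class] built by [propagateAnnotations()].
#' @export
studyCorpus <- function(study) {
  propagateAnnotations(study@dag, study@annotations)
}

#' @describeIn simulateStudy the study's seed set.
#' @export
studySeeds <- function(study) study@seeds

#' @describeIn simulateStudy the planted module (ground truth).
#' @export
studyTruth <- function(study) study@truth

#' @describeIn simulateStudy the simulated interaction graph.
#' @export
studyGraph <- function(study) study@graph

#' Write a synthetic study as a fixture directory
#'
#' Emits exactly the formats the readers consume: `ppi_edges.tsv`
#' (unit-scale edge table), `ontology.obo`, `annotations.gaf`,
#' `seeds.txt`, `truth.gmt` and `params.yaml`.  Same seed, same bytes.
#'
#' @param study a [SyntheticStudy-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writePPITable(study@graph, file.path(dir, "ppi_edges.tsv"))
  writeOBO(study@dag, file.path(dir, "ontology.obo"))
  writeGAF(study@annotations, study@dag, file.path(dir, "annotations.gaf"))
  writeLines(c("# synthetic seed proteins", seedMembers(study@seeds)),
             file.path(dir, "seeds.txt"))
  writeGMT(geneSetCollection(list(planted_module = study@truth),
                             universe = graphNodes(study@graph)),
           file.path(dir, "truth.gmt"))
  p <- study@params
  yaml::write_yaml(list(
    seed = study@seed, nGenes = p@nGenes, moduleSize = p@moduleSize,
    nSeeds = p@nSeeds, pIn = p@pIn, pOut = p@pOut,
    confIn = p@confIn, confOut = p@confOut, nTerms = p@nTerms,
    maxDepth = p@maxDepth, moduleTermCount = p@moduleTermCount,
    sharedAnnotations = p@sharedAnnotations),
    file.path(dir, "params.yaml"))
  invisible(dir)
}
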