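## Disease-specific network construction: nearest-neighbor expansion from
## seeds, then dual edge weights (interaction confidence C from the source
## graph, functional similarity F from the annotation corpus).

#' Nearest-neighbor expansion of a seed set
#'
#' Candidates are the direct interaction neighbors of the seeds present in
#' the graph, minus every seed (seeds are never candidates).  Seeds absent
#' from the graph are dropped with a warning; if no seed is present the
#' expansion fails.
#'
#' @param graph a [WeightedPPIGraph-class].
#' @param seeds a [SeedSet-class].
#' @return list with sorted character vectors `seedsPresent` and
#'   `candidates`.
#' @export
expandSeeds <- function(graph, seeds) {
  stopifnot(is(graph, "WeightedPPIGraph"), is(seeds, "SeedSet"))
  members <- seedMembers(seeds)
  present <- sort(intersect(members, graphNodes(graph)))
  absent <- setdiff(members, present)
  if (!length(present))
    gbaDataError("no seed found in interaction data (label '%s')",
                 seedLabel(seeds))
  if (length(absent))
    warning(sprintf("%d seed(s) absent from the interaction graph: %s",
                    length(absent), paste(absent, collapse = ", ")),
            call. = FALSE)
  candidates <- sort(setdiff(ppiNeighbors(graph, present), members))
  list(seedsPresent = present, candidates = candidates)
}

#' Build a weighted disease-specific PPI network
#'
#' Expands the seeds to their direct neighbors and attaches two weights to
#' every retained edge: the interaction confidence `C` from the source
#' graph and the functional similarity `F` from the annotation corpus
#' (fallback value when either endpoint lacks usable annotation).  With
#' the default `"induced"` policy all source-graph edges among
#' seeds+candidates are kept, including candidate-candidate edges; with
#' `"seed_incident"` only edges touching a seed are kept.
#'
#' @param graph a [WeightedPPIGraph-class].
#' @param seeds a [SeedSet-class].
#' @param corpus an [AnnotationCorpus-class], or `NULL` to use the
#'   fallback similarity for every edge.
#' @param config an [edgeWeightConfig()].
#' @param fsim optional precomputed [similarityProvider()] (shared caches
#'   across networks); built from `corpus` when `NULL`.
#' @return A [DiseaseNetwork-class].
#' @export
buildDiseaseNetwork <- function(graph, seeds, corpus = NULL,
                                config = edgeWeightConfig(), fsim = NULL) {
  ex <- expandSeeds(graph, seeds)
  members <- c(ex$seedsPresent, ex$candidates)
  e <- graphEdges(graph)
  inA <- e$a %in% members
  inB <- e$b %in% members
  keep <- if (config@policy == "induced") inA & inB else
    (e$a %in% ex$seedsPresent & inB) | (e$b %in% ex$seedsPresent & inA)
  e <- e[keep, , drop = FALSE]
  if (is.null(fsim) && !is.null(corpus))
    fsim <- similarityProvider(corpus, config@sim, fallback = config@fallback)
  F <- if (is.null(fsim)) rep(config@fallback, nrow(e)) else
    mapply(fsim, e$a, e$b, USE.NAMES = FALSE)
  edges <- data.frame(a = e$a, b = e$b, C = e$confidence, F = as.numeric(F),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  new("DiseaseNetwork", label = seedLabel(seeds), seeds = ex$seedsPresent,
      candidates = ex$candidates, edges = edges, policy = config@policy)
}

#' Write a disease network as node and edge tables
#'
#' @param net a [DiseaseNetwork-class].
#' @param nodeSink,edgeSink file paths or connections.
#' @export
writeDiseaseNetwork <- function(net, nodeSink, edgeSink) {
  nodes <- data.frame(id = c(net@seeds, net@candidates),
                      is_seed = c(rep(1L, length(net@seeds)),
                                  rep(0L, length(net@candidates))))
  nodes <- nodes[order(nodes$id), ]
  writeLines(c("id\tis_seed", sprintf("%s\t%d", nodes$id, nodes$is_seed)),
             nodeSink)
  e <- net@edges
  writeLines(c("a\tb\tC\tF",
               sprintf("%s\t%s\t%.10g\t%.10g", e$a, e$b, e$C, e$F)),
             edgeSink)
  invisible(net)
}
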