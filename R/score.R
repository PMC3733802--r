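## Guilt-by-association disease relevance score.
##
## For protein i with source-graph neighbors N(i), network-membership
## indicator I(.), confidence C and functional similarity F:
##   S(i) = sum_{j in N(i)} (alpha C_ij + beta F_ij) I(j)
##        - sum_{j in N(i)} (alpha C_ij + beta F_ij) (1 - I(j))
## More in-network neighbors, higher confidences and higher functional
## similarities raise the score; promiscuous out-of-network connections
## lower it.  The formula is pluggable (scoreParams(formula = "plugin")).

## Neighbor table of one node: j, C, F, I.  F comes from the network edge
## when available, otherwise from the similarity provider, otherwise the
## fallback.
neighborData <- function(i, net, graph, fsim = NULL, fallback = 0) {
  e <- graphEdges(graph)
  hitA <- e$a == i
  hitB <- e$b == i
  j <- c(e$b[hitA], e$a[hitB])
  C <- c(e$confidence[hitA], e$confidence[hitB])
  if (!length(j))
    return(data.frame(j = character(), C = numeric(), F = numeric(),
                      I = integer(), stringsAsFactors = FALSE))
  netF <- setNames(net@edges$F, pairKey(net@edges$a, net@edges$b))
  Fv <- unname(netF[pairKey(rep(i, length(j)), j)])
  miss <- is.na(Fv)
  if (any(miss))
    Fv[miss] <- if (is.null(fsim)) fallback else
      vapply(j[miss], function(x) fsim(i, x), 0, USE.NAMES = FALSE)
  I <- unname(networkMembership(net, j))
  ord <- order(j)
  data.frame(j = j[ord], C = C[ord], F = Fv[ord], I = I[ord],
             stringsAsFactors = FALSE)
}

applyFormula <- function(nd, params) {
  if (params@formula == "plugin")
    return(params@plugin[[1L]](nd, params@alpha, params@beta))
  if (!nrow(nd)) return(0)
  sum((params@alpha * nd$C + params@beta * nd$F) * (2 * nd$I - 1))
}

#' Disease relevance score of one protein
#'
#' @param i protein identifier (must belong to the disease network).
#' @param net a [DiseaseNetwork-class].
#' @param graph the source [WeightedPPIGraph-class] (neighborhoods `N(i)`
#'   are taken here, so out-of-network connections are penalized).
#' @param params a [scoreParams()].
#' @param fsim optional [similarityProvider()] supplying `F` for
#'   neighbor pairs outside the network's edge set (fallback 0 otherwise).
#' @return the score S(i); 0 for an isolated protein.
#' @export
diseaseRelevanceScore <- function(i, net, graph, params = scoreParams(),
                                  fsim = NULL) {
  if (!(i %in% c(net@seeds, net@candidates)))
    gbaDataError("protein '%s' is not in the disease network", i)
  applyFormula(neighborData(i, net, graph, fsim), params)
}

#' Score and rank every protein of a disease network
#'
#' Seeds and candidates are all scored; ranks (1 = best) are assigned to
#' candidates only, by descending score with ties broken by identifier
#' lexicographic order.  Seeds are never ranked among candidates.
#'
#' @inheritParams diseaseRelevanceScore
#' @param accessions optional named accession map carried into
#'   [writeRanking()] output.
#' @return A [ScoreTable-class].
#' @export
scoreAll <- function(net, graph, params = scoreParams(), fsim = NULL,
                     accessions = character()) {
  proteins <- c(net@seeds, net@candidates)
  isSeed <- c(rep(TRUE, length(net@seeds)),
              rep(FALSE, length(net@candidates)))
  ## vectorized accumulation of signed alpha*C + beta*F over all
  ## source-graph edges incident to network members
  prof <- scoreProfiles(net, graph, fsim)
  if (params@formula == "plugin") {
    scores <- vapply(proteins, function(p)
      applyFormula(neighborData(p, net, graph, fsim), params), 0,
      USE.NAMES = TRUE)
  } else {
    scores <- params@alpha * prof$aC[proteins] + params@beta * prof$aF[proteins]
    names(scores) <- proteins
  }
  tb <- data.frame(protein = proteins, isSeed = isSeed,
                   score = unname(scores), rank = NA_integer_,
                   stringsAsFactors = FALSE)
  cand <- which(!tb$isSeed)
  if (length(cand)) {
    ord <- cand[order(-tb$score[cand], tb$protein[cand])]
    tb$rank[ord] <- seq_along(ord)
  }
  fp <- sprintf("%s|%d seeds|%d candidates|%d edges|policy=%s",
                net@label, length(net@seeds), length(net@candidates),
                nrow(net@edges), net@policy)
  new("ScoreTable", table = tb, alpha = params@alpha, beta = params@beta,
      accessions = accessions, fingerprint = fp)
}

## Per-node signed aggregates: aC(i) = sum_j C_ij (2 I(j) - 1), aF likewise
## with F.  The default score is then alpha*aC + beta*aF, which makes grid
## search over (alpha, beta) a reweighting rather than a re-summation.
scoreProfiles <- function(net, graph, fsim = NULL, fallback = 0,
                          nodes = NULL) {
  members <- c(net@seeds, net@candidates)
  if (is.null(nodes)) nodes <- members
  e <- graphEdges(graph)
  keep <- e$a %in% nodes | e$b %in% nodes
  e <- e[keep, , drop = FALSE]
  netF <- setNames(net@edges$F, pairKey(net@edges$a, net@edges$b))
  Fv <- unname(netF[pairKey(e$a, e$b)])
  miss <- which(is.na(Fv))
  if (length(miss))
    Fv[miss] <- if (is.null(fsim)) fallback else
      mapply(fsim, e$a[miss], e$b[miss], USE.NAMES = FALSE)
  memb <- c(e$a %in% members, e$b %in% members)   # I(a), I(b)
  sgn <- 2 * as.numeric(memb) - 1
  ## contribution of edge (a,b): to node a with sign of I(b), and vice versa
  i <- c(e$a, e$b)
  signedC <- c(e$confidence, e$confidence) * sgn[c(seq_len(nrow(e)) + nrow(e),
                                                   seq_len(nrow(e)))]
  signedF <- c(Fv, Fv) * sgn[c(seq_len(nrow(e)) + nrow(e),
                               seq_len(nrow(e)))]
  aC <- setNames(numeric(length(nodes)), nodes)
  aF <- setNames(numeric(length(nodes)), nodes)
  use <- i %in% nodes
  if (any(use)) {
    sC <- tapply(signedC[use], i[use], sum)
    sF <- tapply(signedF[use], i[use], sum)
    aC[names(sC)] <- as.numeric(sC)
    aF[names(sF)] <- as.numeric(sF)
  }
  list(aC = aC, aF = aF)
}
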