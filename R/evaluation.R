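## Leave-one-out cross-validation, rank-ratio ROC/AUC, hypergeometric
## enrichment, and seed-set overlap reports.

## Per-fold candidate profiles shared by loocv() and gridSearch(): the
## network is rebuilt once per held-out seed; each candidate's signed
## aggregates (aC, aF) are stored so any (alpha, beta) can be ranked
## without re-summation (the default score is linear in alpha and beta).
loocvProfiles <- function(graph, seeds, corpus = NULL,
                          config = edgeWeightConfig(), fsim = NULL) {
  members <- seedMembers(seeds)
  if (length(members) < 2L)
    gbaDataError("leave-one-out cross-validation needs at least 2 seeds")
  if (is.null(fsim) && !is.null(corpus))
    fsim <- similarityProvider(corpus, config@sim, fallback = config@fallback)
  nodes <- graphNodes(graph)
  e <- graphEdges(graph)
  ## functional similarity is a property of the gene pair, not of the fold:
  ## compute once per edge and reuse across every rebuilt network
  Fv <- if (is.null(fsim)) rep(config@fallback, nrow(e)) else
    as.numeric(mapply(fsim, e$a, e$b, USE.NAMES = FALSE))
  idxA <- match(e$a, nodes)
  idxB <- match(e$b, nodes)
  nb <- split(c(idxB, idxA), c(idxA, idxB))
  adj <- vector("list", length(nodes))
  adj[as.integer(names(nb))] <- nb
  seedIdx <- match(members, nodes)          # NA for seeds absent from graph
  if (all(is.na(seedIdx)))
    gbaDataError("no seed found in interaction data (label '%s')",
                 seedLabel(seeds))
  lapply(sort(members), function(held) {
    rem <- setdiff(members, held)
    present <- seedIdx[match(rem, members)]
    present <- present[!is.na(present)]
    if (!length(present))
      gbaDataError("no seed found in interaction data (label '%s')",
                   seedLabel(seeds))
    candIdx <- setdiff(sort(unique(unlist(adj[present], use.names = FALSE))),
                       match(rem, nodes))
    memb <- logical(length(nodes))
    memb[c(present, candIdx)] <- TRUE
    sgnA <- 2 * memb[idxA] - 1               # sign seen from endpoint b
    sgnB <- 2 * memb[idxB] - 1               # sign seen from endpoint a
    grp <- c(idxA, idxB)
    wC <- c(e$confidence * sgnB, e$confidence * sgnA)
    wF <- c(Fv * sgnB, Fv * sgnA)
    keep <- grp %in% candIdx
    cand <- nodes[candIdx]
    aC <- setNames(numeric(length(candIdx)), cand)
    aF <- setNames(numeric(length(candIdx)), cand)
    if (any(keep)) {
      sums <- rowsum(cbind(wC[keep], wF[keep]), grp[keep])
      hit <- nodes[as.integer(rownames(sums))]
      aC[hit] <- sums[, 1L]
      aF[hit] <- sums[, 2L]
    }
    list(heldOut = held, candidates = cand, aC = aC, aF = aF)
  })
}

## Rank each fold's candidates for one (alpha, beta); sentinel = worst
## rank M+1 (with M incremented) for a held-out seed that is not a
## candidate of the rebuilt network.
rankFolds <- function(profiles, alpha, beta) {
  rows <- lapply(profiles, function(f) {
    M <- length(f$candidates)
    S <- alpha * f$aC + beta * f$aF
    ord <- order(-S, f$candidates)
    pos <- match(f$heldOut, f$candidates[ord])
    if (is.na(pos)) {
      M <- M + 1L
      pos <- M
      absent <- TRUE
    } else absent <- FALSE
    data.frame(heldOut = f$heldOut, M = as.integer(M), R = as.integer(pos),
               absent = absent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Leave-one-out cross-validation of seed recovery
#'
#' Each seed in turn is removed from the seed set (joining the candidate
#' pool), the disease network is rebuilt from the remaining seeds, all
#' candidates are scored and ranked, and the held-out seed's rank is
#' recorded.  A held-out seed not adjacent to any remaining seed cannot
#' re-enter the network and receives the sentinel worst rank `M + 1`
#' (with `M` incremented), so that every fold satisfies `1 <= R <= M`.
#'
#' @param graph the source [WeightedPPIGraph-class].
#' @param seeds a [SeedSet-class] with at least two members.
#' @param corpus an [AnnotationCorpus-class] (or `NULL` for fallback
#'   functional similarity).
#' @param params a [scoreParams()].
#' @param config an [edgeWeightConfig()].
#' @param fsim optional shared [similarityProvider()].
#' @return data.frame with one row per fold: `heldOut`, `M` (candidate
#'   count), `R` (held-out rank), `absent`.
#' @export
loocv <- function(graph, seeds, corpus = NULL, params = scoreParams(),
                  config = edgeWeightConfig(), fsim = NULL) {
  profiles <- loocvProfiles(graph, seeds, corpus, config, fsim)
  rankFolds(profiles, params@alpha, params@beta)
}

#' Rank-ratio ROC curve from LOOCV folds
#'
#' Thresholds sweep every achievable rank ratio `k / M_f` (k = 0..M_f,
#' union over folds).  At threshold `r`, sensitivity is the fraction of
#' folds whose held-out seed ranks within the top `floor(r * M_f)`;
#' 1 - specificity is the proportion of non-test candidates ranked in the
#' same top slice, pooled over folds by default (`average = "micro"`) or
#' averaged per fold (`"macro"`).
#'
#' @param folds data.frame from [loocv()] (columns `M`, `R`, optionally
#'   `absent`).
#' @param average `"micro"` (pooled counts, default) or `"macro"`.
#' @param dropAbsent drop folds whose held-out seed was absent from the
#'   rebuilt network instead of keeping their sentinel worst rank.
#' @return A [RocCurve-class] with trapezoidal AUC.
#' @export
rocFromFolds <- function(folds, average = c("micro", "macro"),
                         dropAbsent = FALSE) {
  average <- match.arg(average)
  stopifnot(nrow(folds) >= 1L, all(folds$R >= 1L), all(folds$R <= folds$M))
  if (dropAbsent && "absent" %in% colnames(folds)) {
    folds <- folds[!folds$absent, , drop = FALSE]
    if (!nrow(folds)) gbaDataError("all folds dropped as absent")
  }
  M <- folds$M; R <- folds$R
  thresholds <- sort(unique(c(0, 1, unlist(lapply(unique(M), function(m)
    seq.int(0L, m) / m)))))
  nneg <- pmax(M - 1L, 0L)
  pts <- vapply(thresholds, function(r) {
    t_f <- floor(r * M + 1e-9)
    hit <- R <= t_f
    tpr <- mean(hit)
    inTop <- t_f - as.integer(hit)
    fpr <- if (average == "micro") {
      if (sum(nneg) == 0) r else sum(inTop) / sum(nneg)
    } else {
      ok <- nneg > 0
      if (!any(ok)) r else mean(inTop[ok] / nneg[ok])
    }
    c(fpr = fpr, tpr = tpr)
  }, c(fpr = 0, tpr = 0))
  pts <- as.data.frame(t(pts))
  pts <- pts[order(pts$fpr, pts$tpr), , drop = FALSE]
  pts <- pts[!duplicated(pts), , drop = FALSE]
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (head(pts$tpr, -1L) + pts$tpr[-1L]) / 2)
  new("RocCurve", points = pts, auc = min(max(auc, 0), 1),
      nFolds = nrow(folds))
}

#' Compare AUCs of several ROC curves
#'
#' @param curves named list of [RocCurve-class] objects (internal LOOCV
#'   results or curves built from external ranking files, see
#'   [foldsFromRanking()]).
#' @return data.frame (`method`, `auc`, `nFolds`) in descending AUC order;
#'   ties broken by method name.
#' @export
aucCompare <- function(curves) {
  stopifnot(length(curves) >= 1L, !is.null(names(curves)))
  df <- data.frame(method = names(curves),
                   auc = vapply(curves, rocAUC, 0),
                   nFolds = vapply(curves, function(c) c@nFolds, 0L),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$auc, df$method), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Pseudo-folds from an external ranking file
#'
#' For side-by-side ROC comparison with other prioritization tools: each
#' known positive becomes one pseudo-fold with `M` = number of ranked
#' proteins and `R` = the positive's rank (sentinel `M + 1` when the
#' positive is missing from the ranking).
#'
#' @param ranking data.frame from [readExternalRanking()].
#' @param positives identifiers of known disease proteins.
#' @return folds data.frame compatible with [rocFromFolds()].
#' @export
foldsFromRanking <- function(ranking, positives) {
  stopifnot(length(positives) >= 1L)
  M0 <- nrow(ranking)
  rows <- lapply(sort(positives), function(p) {
    pos <- ranking$rank[match(p, ranking$protein)]
    if (is.na(pos))
      data.frame(heldOut = p, M = M0 + 1L, R = M0 + 1L, absent = TRUE,
                 stringsAsFactors = FALSE)
    else
      data.frame(heldOut = p, M = M0, R = as.integer(pos), absent = FALSE,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment of a top candidate list
#'
#' Upper-tail hypergeometric probability `P(X >= k)` of drawing `k` set
#' members in a top list of size `n` from a universe of size `N`
#' containing `K` set members.  Raw p-values are flagged at `alphaLevel`;
#' an optional Benjamini-Hochberg column is available.
#'
#' @param top character vector of top-ranked identifiers (must be a
#'   subset of the collection's universe).
#' @param sets a [geneSetCollection()].
#' @param alphaLevel significance flag threshold (default 0.05).
#' @param adjust `"none"` (default) or `"BH"` to add an adjusted-p column.
#' @return data.frame sorted by ascending p with columns `set`, `k`, `K`,
#'   `n`, `N`, `p`, `significant` (and `p_adjusted` when requested).
#' @export
hypergeomEnrichment <- function(top, sets, alphaLevel = 0.05,
                                adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is(sets, "GeneSetCollection"))
  top <- unique(as.character(top))
  stray <- setdiff(top, sets@universe)
  if (length(stray))
    gbaDataError("top list contains ids outside the universe: %s",
                 paste(stray, collapse = ", "))
  N <- length(sets@universe)
  n <- length(top)
  rows <- lapply(names(sets@sets), function(nm) {
    members <- sets@sets[[nm]]
    K <- length(members)
    k <- length(intersect(top, members))
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df$significant <- df$p < alphaLevel
  if (adjust == "BH") df$p_adjusted <- stats::p.adjust(df$p, method = "BH")
  df <- df[order(df$p, df$set), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Overlap report for two seed sets
#'
#' @param a,b [SeedSet-class] objects.
#' @return list with `labelA`, `labelB`, `nA`, `nB`, `shared` (sorted) and
#'   `nShared`.
#' @examples
#' setOverlap(cardiomyopathySeeds("DCM"), cardiomyopathySeeds("HCM"))$nShared
#' @export
setOverlap <- function(a, b) {
  stopifnot(is(a, "SeedSet"), is(b, "SeedSet"))
  shared <- sort(intersect(seedMembers(a), seedMembers(b)))
  list(labelA = seedLabel(a), labelB = seedLabel(b),
       nA = length(seedMembers(a)), nB = length(seedMembers(b)),
       shared = shared, nShared = length(shared))
}
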