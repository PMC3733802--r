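## (alpha, beta) screening by LOOCV AUC.

#' Grid search over the score's weighting constants
#'
#' Runs leave-one-out cross-validation and the rank-ratio ROC for every
#' (alpha, beta) combination and selects the pair maximizing AUC (ties
#' broken by smallest alpha, then smallest beta).  Fold networks and
#' functional similarities are computed once and shared across the grid:
#' under the default score form, `S = alpha * aC + beta * aF` per
#' candidate, so each cell is a reweighting of cached aggregates.  A
#' consequence worth knowing: scaling both constants by the same factor
#' leaves every ranking, and hence every AUC, unchanged.
#'
#' @param graph the source [WeightedPPIGraph-class].
#' @param seeds a [SeedSet-class].
#' @param corpus an [AnnotationCorpus-class] or `NULL`.
#' @param alphas,betas positive values to screen (default `1:10`, the
#'   conventional 100-cell integer grid).
#' @param config an [edgeWeightConfig()].
#' @param average specificity pooling passed to [rocFromFolds()].
#' @param dropAbsent passed to [rocFromFolds()].
#' @param fsim optional shared [similarityProvider()].
#' @return A [GridResult-class].
#' @export
gridSearch <- function(graph, seeds, corpus = NULL, alphas = 1:10,
                       betas = 1:10, config = edgeWeightConfig(),
                       average = "micro", dropAbsent = FALSE, fsim = NULL) {
  stopifnot(length(alphas) >= 1L, length(betas) >= 1L,
            all(alphas > 0), all(betas > 0))
  profiles <- loocvProfiles(graph, seeds, corpus, config, fsim)
  combos <- expand.grid(alpha = as.numeric(alphas),
                        beta = as.numeric(betas),
                        KEEP.OUT.ATTRS = FALSE)
  combos$auc <- vapply(seq_len(nrow(combos)), function(i) {
    folds <- rankFolds(profiles, combos$alpha[i], combos$beta[i])
    rocAUC(rocFromFolds(folds, average = average, dropAbsent = dropAbsent))
  }, 0)
  best <- combos[order(-combos$auc, combos$alpha, combos$beta), ][1L, ]
  new("GridResult", grid = combos, bestAlpha = best$alpha,
      bestBeta = best$beta, objective = best$auc)
}

#' Write a grid result as a tab-delimited alpha-by-beta matrix
#'
#' @param result a [GridResult-class].
#' @param sink file path or connection.
#' @export
writeGridMatrix <- function(result, sink) {
  m <- gridMatrix(result)
  lines <- c(paste(c("alpha\\beta", colnames(m)), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], sprintf("%.6g", m[i, ])),
                     collapse = "\t"), ""))
  writeLines(lines, sink)
  invisible(result)
}
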