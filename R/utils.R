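## Internal helpers shared across modules.

## Classed conditions so the CLI can map failures to exit codes.
gbaFormatError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gba_format_error", "gba_error", "error")))
}

gbaDataError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gba_data_error", "gba_error", "error")))
}

gbaUsageError <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("gba_usage_error", "gba_error", "error")))
}

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Canonical unordered-pair representation: a < b lexicographically.
canonicalPairs <- function(a, b) {
  swap <- b < a
  data.frame(a = ifelse(swap, b, a), b = ifelse(swap, a, b),
             stringsAsFactors = FALSE)
}

pairKey <- function(a, b) {
  p <- canonicalPairs(a, b)
  paste(p$a, p$b, sep = "\r")
}

## Identifier validation: non-empty token without internal whitespace.
checkProteinIds <- function(ids, what = "identifier") {
  bad <- !nzchar(ids) | grepl("[[:space:]]", ids)
  if (any(bad))
    gbaFormatError("invalid %s: '%s' (empty or contains whitespace)",
                   what, ids[which(bad)[1L]])
  invisible(ids)
}

## Read raw lines from a path or connection.
readSourceLines <- function(source) {
  lines <- readLines(source, warn = FALSE)
  lines
}

`%||%` <- function(x, y) if (is.null(x)) y else x
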