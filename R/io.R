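## Readers and writers for every external representation the tool touches.
## All identifiers are treated as opaque case-sensitive tokens; the
## gene-symbol vs protein-accession distinction is data, not logic.

#' Read a weighted PPI edge table
#'
#' Tab- or comma-delimited triples `id_a, id_b, score` (delimiter
#' autodetected from the first line; a non-numeric third field on the first
#' line is treated as a header).  Confidences are normalized to \[0,1\]:
#' `scale = "raw_999"` divides STRING-style 0-999 combined scores by 1000.
#' Duplicate unordered pairs are collapsed keeping the maximum confidence;
#' self-interactions are dropped with a warning.
#'
#' @param source file path or connection.
#' @param scale `"unit"` (scores already on \[0,1\]) or `"raw_999"`.
#' @return A [WeightedPPIGraph-class].
#' @examples
#' f <- tempfile()
#' writeLines(c("A\tB\t900", "B\tC\t500", "A\tC\t100"), f)
#' readPPITable(f, scale = "raw_999")
#' @export
readPPITable <- function(source, scale = c("unit", "raw_999")) {
  scale <- match.arg(scale)
  lines <- readSourceLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) gbaFormatError("empty interaction table")
  delim <- if (grepl("\t", lines[1L])) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  start <- 1L
  ## a non-numeric third field on the first line is a header -- but only
  ## when data lines follow, so a lone malformed row still errors by name
  if (length(fields) >= 2L &&
      suppressWarnings(is.na(as.numeric(fields[[1L]][3L]))))
    start <- 2L
  rows <- lapply(seq.int(start, length(fields)), function(i) {
    f <- trimws(fields[[i]])
    if (length(f) < 3L)
      gbaFormatError("line %d: expected at least 3 columns, got %d",
                     i, length(f))
    sc <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(sc))
      gbaFormatError("line %d: non-numeric score '%s'", i, f[3L])
    if (sc < 0) gbaFormatError("line %d: negative score %s", i, f[3L])
    list(a = f[1L], b = f[2L], score = sc, line = i)
  })
  a <- vapply(rows, `[[`, "", "a")
  b <- vapply(rows, `[[`, "", "b")
  sc <- vapply(rows, `[[`, 0, "score")
  checkProteinIds(c(a, b), "protein identifier")
  conf <- if (scale == "raw_999") sc / 1000 else sc
  if (any(conf > 1))
    gbaFormatError("line %d: confidence %.4g exceeds 1 on the '%s' scale",
                   vapply(rows, `[[`, 0L, "line")[which(conf > 1)[1L]],
                   max(conf), scale)
  weightedPPIGraph(data.frame(a = a, b = b, confidence = conf,
                              stringsAsFactors = FALSE))
}

#' Write a PPI edge table
#'
#' @param graph a [WeightedPPIGraph-class].
#' @param sink file path or connection.
#' @export
writePPITable <- function(graph, sink) {
  e <- graphEdges(graph)
  lines <- c("id_a\tid_b\tscore",
             sprintf("%s\t%s\t%.10g", e$a, e$b, e$confidence))
  writeLines(lines, sink)
  invisible(sink)
}

#' Read a seed-protein list
#'
#' One identifier per line, optional second whitespace-separated column
#' with the protein accession; `#` comment lines are skipped.  Duplicates
#' are an error.
#'
#' @param source file path or connection.
#' @param label disease label attached to the set.
#' @return A [SeedSet-class].
#' @seealso [cardiomyopathySeeds()] for the bundled cardiomyopathy lists.
#' @export
readSeedList <- function(source, label = "disease") {
  lines <- readSourceLines(source)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) gbaFormatError("seed list is empty")
  fields <- strsplit(lines, "[[:space:]]+")
  ids <- vapply(fields, `[[`, "", 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup))
    gbaFormatError("duplicate seed identifier '%s'", dup[1L])
  acc <- vapply(fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_, "")
  accessions <- setNames(acc[!is.na(acc)], ids[!is.na(acc)])
  seedSet(ids, label = label, accessions = accessions)
}

#' Bundled cardiomyopathy seed-protein fixtures
#'
#' Seed gene lists (official symbols with protein accessions) for dilated
#' (DCM, 33 genes), hypertrophic (HCM, 24 genes) and arrhythmogenic right
#' ventricular (ARVC, 9 genes) cardiomyopathy, as curated from OMIM.
#'
#' @param disease one of `"DCM"`, `"HCM"`, `"ARVC"`.
#' @return A [SeedSet-class].
#' @examples
#' length(seedMembers(cardiomyopathySeeds("DCM")))  # 33
#' @export
cardiomyopathySeeds <- function(disease = c("DCM", "HCM", "ARVC")) {
  disease <- match.arg(disease)
  path <- system.file("extdata", sprintf("seeds_%s.txt", tolower(disease)),
                      package = "gbaNet", mustWork = TRUE)
  readSeedList(path, label = disease)
}

## OBO namespace strings -> short codes.
.nsCode <- c(biological_process = "BP", molecular_function = "MF",
             cellular_component = "CC", BP = "BP", MF = "MF", CC = "CC")

#' Read an OBO 1.2 ontology
#'
#' Only `[Term]` stanzas are consumed; obsolete terms are skipped.  Edges
#' follow `is_a` lines child-to-parent; `relationship: part_of` lines are
#' included only when `includePartOf = TRUE`.  The result is checked to be
#' acyclic (an error lists one offending cycle).
#'
#' @param source file path or connection.
#' @param includePartOf also traverse `part_of` relations (off by default).
#' @return An [OntologyDAG-class].
#' @export
readOBO <- function(source, includePartOf = FALSE) {
  lines <- readSourceLines(source)
  ## stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) gbaFormatError("no stanzas found in OBO input")
  ends <- c(starts[-1L] - 1L, length(lines))
  terms <- list(); edges <- list()
  for (k in seq_along(starts)) {
    if (trimws(lines[starts[k]]) != "[Term]") next
    body <- lines[seq.int(starts[k], ends[k])][-1L]
    body <- body[nzchar(trimws(body))]
    getv <- function(tag) {
      hit <- body[startsWith(body, paste0(tag, ":"))]
      trimws(sub(paste0("^", tag, ":"), "", hit))
    }
    id <- getv("id")
    if (!length(id) || !nzchar(id[1L]))
      gbaFormatError("[Term] stanza without an id (stanza %d)", k)
    id <- id[1L]
    if (any(grepl("^true", getv("is_obsolete")))) next
    nm <- getv("name"); nm <- if (length(nm)) nm[1L] else NA_character_
    ns <- getv("namespace")
    ns <- if (length(ns)) .nsCode[[ns[1L]]] %||% ns[1L] else "BP"
    parents <- sub("\\s*!.*$", "", getv("is_a"))
    rel <- character(0)
    if (includePartOf) {
      rl <- getv("relationship")
      rl <- sub("\\s*!.*$", "", rl)
      po <- grepl("^part_of\\s", rl)
      rel <- trimws(sub("^part_of\\s+", "", rl[po]))
    }
    terms[[id]] <- data.frame(id = id, name = nm, namespace = ns,
                              stringsAsFactors = FALSE)
    if (length(parents) || length(rel))
      edges[[id]] <- data.frame(
        child = id, parent = c(parents, rel),
        relation = c(rep("is_a", length(parents)),
                     rep("part_of", length(rel))),
        stringsAsFactors = FALSE)
  }
  if (!length(terms)) gbaFormatError("no usable [Term] stanzas in OBO input")
  termDf <- do.call(rbind, terms)
  edgeDf <- if (length(edges)) do.call(rbind, edges) else
    data.frame(child = character(), parent = character(),
               relation = character(), stringsAsFactors = FALSE)
  ## edges to obsolete/undeclared parents: keep the parent as a bare term
  missing <- setdiff(edgeDf$parent, termDf$id)
  if (length(missing))
    termDf <- rbind(termDf,
                    data.frame(id = missing, name = NA_character_,
                               namespace = termDf$namespace[
                                 match(edgeDf$child[match(missing, edgeDf$parent)],
                                       termDf$id)],
                               stringsAsFactors = FALSE))
  rownames(termDf) <- NULL
  rownames(edgeDf) <- NULL
  ontologyDAG(termDf, edgeDf)
}

#' Write an ontology in OBO 1.2 format
#'
#' @param dag an [OntologyDAG-class].
#' @param sink file path or connection.
#' @export
writeOBO <- function(dag, sink) {
  ns <- c(BP = "biological_process", MF = "molecular_function",
          CC = "cellular_component")
  tm <- ontologyTerms(dag)
  ed <- ontologyEdges(dag)
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(tm))) {
    id <- tm$id[i]
    stanza <- c("[Term]", paste0("id: ", id),
                paste0("name: ", if (is.na(tm$name[i])) id else tm$name[i]),
                paste0("namespace: ", ns[[tm$namespace[i]]] %||% tm$namespace[i]))
    pe <- ed[ed$child == id, , drop = FALSE]
    for (j in seq_len(nrow(pe)))
      stanza <- c(stanza, if (pe$relation[j] == "is_a")
        paste0("is_a: ", pe$parent[j]) else
          paste0("relationship: part_of ", pe$parent[j]))
    out <- c(out, stanza, "")
  }
  writeLines(out, sink)
  invisible(sink)
}

#' Read GAF 2.x gene annotations
#'
#' Comment lines (`!`) are skipped; rows whose qualifier contains `NOT`
#' are dropped; rows with an excluded evidence code are dropped.  Only
#' direct annotations are returned (ancestor propagation is done by
#' [propagateAnnotations()]).  Genes are keyed by the DB object symbol
#' (column 3).
#'
#' @param source file path or connection.
#' @param excludeEvidence evidence codes to drop (default none: the
#'   corpus includes all evidence, IEA too).
#' @return Named list: gene -> character vector of term ids.
#' @export
readGAF <- function(source, excludeEvidence = character()) {
  lines <- readSourceLines(source)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  ann <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 15L)
      gbaFormatError("GAF line %d: expected >= 15 columns, got %d",
                     i, length(f))
    qualifier <- f[4L]
    if (grepl("(^|\\|)NOT($|\\|)", qualifier)) next
    if (f[7L] %in% excludeEvidence) next
    gene <- f[3L]; term <- f[5L]
    ann[[gene]] <- c(ann[[gene]], term)
  }
  lapply(ann, function(v) sort(unique(v)))
}

#' Write annotations as GAF 2.1
#'
#' @param annotations named list gene -> term ids.
#' @param dag an [OntologyDAG-class] supplying term namespaces (aspect
#'   column).
#' @param sink file path or connection.
#' @export
writeGAF <- function(annotations, dag, sink) {
  aspect <- c(BP = "P", MF = "F", CC = "C")
  nsOf <- setNames(ontologyTerms(dag)$namespace, ontologyTerms(dag)$id)
  out <- c("!gaf-version: 2.1")
  for (gene in names(annotations)) {
    for (term in annotations[[gene]]) {
      out <- c(out, paste(
        "SYN", gene, gene, "", term, "SYN_REF:0000001", "IEA", "",
        aspect[nsOf[[term]]] %||% "P", gene, "", "protein",
        "taxon:9606", "20130805", "SYN", "", "", sep = "\t"))
    }
  }
  writeLines(out, sink)
  invisible(sink)
}

#' Read gene sets in GMT format
#'
#' One set per line: `set_name<TAB>description<TAB>member...`.
#'
#' @param source file path or connection.
#' @param universe optional explicit universe; defaults to the union of
#'   all sets.
#' @return A [geneSetCollection()].
#' @export
readGMT <- function(source, universe = NULL) {
  lines <- readSourceLines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) gbaFormatError("empty GMT input")
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      gbaFormatError("GMT line %d: expected name, description, members", i)
    sets[[f[1L]]] <- f[-(1:2)]
  }
  geneSetCollection(sets, universe = universe)
}

#' Write gene sets in GMT format
#'
#' @param collection a [geneSetCollection()].
#' @param sink file path or connection.
#' @export
writeGMT <- function(collection, sink) {
  lines <- vapply(names(collection@sets), function(nm)
    paste(c(nm, "synthetic", collection@sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, sink)
  invisible(sink)
}

#' Write a ranked candidate table
#'
#' Tab-delimited `protein  accession  rank  score` in rank order; unknown
#' accessions are written as `-`.  Scores are written with 6 significant
#' digits and round-trip through [readRanking()] at that precision.
#'
#' @param table a [ScoreTable-class] (must be ranked).
#' @param sink file path or connection.
#' @param top optional truncation to the best `top` candidates.
#' @export
writeRanking <- function(table, sink, top = NULL) {
  stopifnot(is(table, "ScoreTable"))
  tb <- table@table
  cand <- tb[!tb$isSeed, , drop = FALSE]
  if (nrow(cand) && anyNA(cand$rank))
    gbaDataError("score table is unranked; run scoreAll() first")
  cand <- cand[order(cand$rank), , drop = FALSE]
  if (!is.null(top)) {
    if (top > nrow(cand))
      warning(sprintf("requested top %d but only %d candidates", top,
                      nrow(cand)), call. = FALSE)
    cand <- head(cand, top)
  }
  acc <- table@accessions[cand$protein]
  acc[is.na(acc)] <- "-"
  lines <- c("protein\taccession\trank\tscore",
             sprintf("%s\t%s\t%d\t%.6g", cand$protein, acc,
                     as.integer(cand$rank), cand$score))
  writeLines(lines, sink)
  invisible(sink)
}

#' Read a ranking written by [writeRanking()]
#'
#' @param source file path or connection.
#' @return data.frame with columns `protein`, `accession`, `rank`, `score`.
#' @export
readRanking <- function(source) {
  lines <- readSourceLines(source)
  lines <- lines[nzchar(lines)]
  if (!length(lines) || !startsWith(lines[1L], "protein"))
    gbaFormatError("not a ranking file (missing header)")
  if (length(lines) == 1L)
    return(data.frame(protein = character(), accession = character(),
                      rank = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines[-1L], "\t", fixed = TRUE)
  data.frame(protein = vapply(f, `[[`, "", 1L),
             accession = vapply(f, `[[`, "", 2L),
             rank = as.integer(vapply(f, `[[`, "", 3L)),
             score = as.numeric(vapply(f, `[[`, "", 4L)),
             stringsAsFactors = FALSE)
}

#' Read an external ranking file for method comparison
#'
#' Two tab- or comma-delimited columns: protein and score-or-rank.  With
#' `type = "score"` larger is better; with `type = "rank"` smaller is
#' better.
#'
#' @param source file path or connection.
#' @param type `"score"` or `"rank"`.
#' @return data.frame with columns `protein`, `rank` (1 = best, ties
#'   broken by identifier).
#' @export
readExternalRanking <- function(source, type = c("score", "rank")) {
  type <- match.arg(type)
  lines <- readSourceLines(source)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) gbaFormatError("empty ranking input")
  delim <- if (grepl("\t", lines[1L])) "\t" else ","
  f <- strsplit(lines, delim, fixed = TRUE)
  if (suppressWarnings(is.na(as.numeric(f[[1L]][2L])))) f <- f[-1L]
  protein <- vapply(f, function(x) trimws(x[1L]), "")
  value <- as.numeric(vapply(f, function(x) trimws(x[2L]), ""))
  if (anyNA(value)) gbaFormatError("non-numeric value in ranking input")
  ord <- if (type == "score") order(-value, protein) else
    order(value, protein)
  data.frame(protein = protein[ord], rank = seq_along(protein),
             stringsAsFactors = FALSE)
}
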