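# Network assembly from flat-file inputs: pathway-gene filtering, DE
# retention, hub selection on interactome degree, intermediary insertion
# along short admissible paths, TF enrichment, and sign resolution into
# nested canalyzing rules.

#' Distinct-partner degree in an interactome
#'
#' Number of distinct interaction partners of each node: redundant
#' evidence lines are collapsed and a self-interaction contributes one
#' partner (the node itself), so hubs are ranked by how many different
#' proteins they touch rather than by evidence volume.
#'
#' @param graph an igraph object (directed or not).
#' @param v node names to report; defaults to all nodes. Names absent
#'   from the graph get degree 0.
#' @return named integer vector.
#' @export
distinctDegree <- function(graph, v = NULL) {
  el <- igraph::as_edgelist(graph)
  partners <- c(split(el[, 2], el[, 1]), split(el[, 1], el[, 2]))
  partners <- tapply(unlist(partners, use.names = FALSE),
                     rep(names(partners), lengths(partners)),
                     function(x) length(unique(x)))
  all <- setNames(integer(length(igraph::V(graph))),
                  igraph::V(graph)$name)
  all[names(partners)] <- as.integer(partners)
  if (is.null(v)) return(all)
  out <- setNames(integer(length(v)), v)
  hit <- intersect(v, names(all))
  out[hit] <- all[hit]
  out
}

#' Construction configuration
#'
#' Collects the tunable parameters of network assembly. Defaults follow
#' the reference procedure: hubs need at least 50 distinct interactome
#' partners; intermediary paths may use up to 3 internal vertices;
#' intermediaries must be expressed above the low-expression threshold in
#' the reference sample (default: the 10th percentile of that sample's
#' nonzero values); canalyzing rules default to inhibitor-dominant logic.
#'
#' @param minHubDegree minimal distinct-partner count for hub selection
#'   (boundary inclusive).
#' @param maxIntermediaries maximal internal vertices on an admitted
#'   connecting path.
#' @param lowExpressionThreshold expression value an intermediary must
#'   exceed in the reference sample; `NULL` uses the 10th percentile of
#'   nonzero reference values.
#' @param referenceSample column of the expression table used for the
#'   intermediary expression check; `NULL` uses the first column.
#' @param seedGenes genes added to the seed set by hand (provenance
#'   `"manual"`).
#' @param ncfScheme `"inhibitor_dominant"` or `"activator_dominant"`.
#' @param unsignedPolicy what to do with an edge no sign source covers:
#'   `"error"` (default) or `"activation"` (logged fallback).
#' @param tfModeAsSign should TF regulation modes stand in for missing
#'   sign-table entries (default TRUE, logged)?
#' @return list of class `ConstructionConfig`.
#' @export
constructionConfig <- function(minHubDegree = 50L,
                               maxIntermediaries = 3L,
                               lowExpressionThreshold = NULL,
                               referenceSample = NULL,
                               seedGenes = character(),
                               ncfScheme = c("inhibitor_dominant",
                                             "activator_dominant"),
                               unsignedPolicy = c("error", "activation"),
                               tfModeAsSign = TRUE) {
  stopifnot(minHubDegree >= 1L, maxIntermediaries >= 0L)
  structure(list(minHubDegree = as.integer(minHubDegree),
                 maxIntermediaries = as.integer(maxIntermediaries),
                 lowExpressionThreshold = lowExpressionThreshold,
                 referenceSample = referenceSample,
                 seedGenes = seedGenes,
                 ncfScheme = match.arg(ncfScheme),
                 unsignedPolicy = match.arg(unsignedPolicy),
                 tfModeAsSign = isTRUE(tfModeAsSign)),
            class = "ConstructionConfig")
}

#' Keep pathway genes present in the expression data
#'
#' A pathway gene is retained iff it appears as a row in at least one of
#' the two expression tables (tumor or control line); genes measured in
#' neither cannot be compared and are excluded.
#'
#' @param pathways named list of gene vectors.
#' @param tumorExpr,controlExpr expression matrices with gene row names.
#' @return list with `genes` (union of retained genes) and `perPathway`
#'   (data.frame pathway, n, retained, excluded).
#' @export
selectExpressedPathwayGenes <- function(pathways, tumorExpr, controlExpr) {
  stopifnot(length(pathways) >= 1L)
  if (!nrow(tumorExpr) || !nrow(controlExpr))
    stop("expression tables must be non-empty")
  measured <- union(rownames(tumorExpr), rownames(controlExpr))
  kept <- lapply(pathways, intersect, y = measured)
  for (p in names(pathways)) {
    if (length(pathways[[p]]) && !length(kept[[p]]))
      warning("pathway '", p, "' has no gene in the expression data")
  }
  list(genes = unique(unlist(kept)),
       perPathway = data.frame(
         pathway = names(pathways),
         n = lengths(pathways),
         retained = lengths(kept),
         excluded = lengths(pathways) - lengths(kept),
         row.names = NULL, stringsAsFactors = FALSE))
}

#' Retain differentially expressed genes
#'
#' Keeps genes whose DE status is `up` or `down`; genes missing from the
#' DE table are treated as not significant (with a warning).
#'
#' @param genes candidate gene symbols.
#' @param de DE status data.frame (columns `gene`, `status`).
#' @return list with `genes`, `status` (named vector over the retained
#'   genes), and `counts` (up/down).
#' @export
retainDifferential <- function(genes, de) {
  status <- setNames(de$status, de$gene)[genes]
  missing <- is.na(status)
  if (any(missing)) {
    warning(sum(missing), " gene(s) missing from the DE table treated as ns")
    status[missing] <- "ns"
  }
  names(status) <- genes
  keep <- status %in% c("up", "down")
  if (!any(keep))
    warning("no differentially expressed genes retained")
  list(genes = genes[keep],
       status = status[keep],
       counts = c(up = sum(status == "up"), down = sum(status == "down")))
}

#' Select interactome hubs
#'
#' Retains the genes with at least `minHubDegree` distinct interaction
#' partners (boundary inclusive: exactly 50 partners passes the default).
#' Genes absent from the interactome have degree 0.
#'
#' @param genes candidate gene symbols.
#' @param interactome igraph object.
#' @param minHubDegree degree cutoff, default 50.
#' @return list with `genes` (selected hubs) and `degree` (named vector
#'   over all candidates).
#' @export
selectHubs <- function(genes, interactome, minHubDegree = 50L) {
  deg <- distinctDegree(interactome, genes)
  list(genes = genes[deg >= minHubDegree], degree = deg)
}

#' Connect seed genes through admissible intermediaries
#'
#' For every seed pair without a direct interactome edge, admits the
#' shortest interactome path with at most `maxIntermediaries` internal
#' vertices, every internal vertex of which is present in the expression
#' table and above the low-expression threshold in the reference sample.
#' Among equal-length paths the lexicographically smallest internal
#' vertex tuple wins, so construction is reproducible. Seed pairs with no
#' admissible path stay unconnected and are reported.
#'
#' @param seeds seed gene symbols.
#' @param interactome igraph object.
#' @param expr expression matrix (gene rows) supplying the reference
#'   sample for the intermediary check.
#' @param config a [constructionConfig()].
#' @return list with `nodes` (data.frame node, provenance, degree),
#'   `edges` (data.frame source, target, directed, sign, provenance) and
#'   `unconnected` (data.frame a, b, reason).
#' @export
connectWithIntermediaries <- function(seeds, interactome, expr,
                                      config = constructionConfig()) {
  refCol <- config$referenceSample %||% colnames(expr)[1]
  refExpr <- expr[, refCol]
  names(refExpr) <- rownames(expr)
  thr <- config$lowExpressionThreshold %||%
    unname(stats::quantile(refExpr[refExpr > 0], 0.1))
  vnames <- igraph::V(interactome)$name
  admissible <- setdiff(
    intersect(vnames, names(refExpr)[refExpr > thr]), seeds)
  present <- intersect(seeds, vnames)
  gAdm <- igraph::induced_subgraph(
    interactome, igraph::V(interactome)[name %in% c(present, admissible)])
  deg <- distinctDegree(interactome)

  edges <- data.frame(source = character(), target = character(),
                      directed = logical(), sign = character(),
                      provenance = character(), stringsAsFactors = FALSE)
  addEdge <- function(a, b, provenance) {
    edges <<- rbind(edges, data.frame(
      source = a, target = b, directed = FALSE, sign = NA_character_,
      provenance = provenance, stringsAsFactors = FALSE))
  }
  intermediaries <- character()
  unconnected <- data.frame(a = character(), b = character(),
                            reason = character(), stringsAsFactors = FALSE)
  seedsSorted <- sort(seeds)
  gAdmNames <- igraph::V(gAdm)$name
  for (i in seq_along(seedsSorted)) {
    for (j in seq_len(i - 1L)) {
      a <- seedsSorted[j]; b <- seedsSorted[i]
      if (a %in% present && b %in% present &&
          igraph::are_adjacent(interactome, a, b)) {
        addEdge(a, b, "interactome")
        next
      }
      if (!(a %in% gAdmNames) || !(b %in% gAdmNames)) {
        unconnected <- rbind(unconnected, data.frame(
          a = a, b = b, reason = "no admissible path",
          stringsAsFactors = FALSE))
        next
      }
      sp <- suppressWarnings(
        igraph::all_shortest_paths(gAdm, from = a, to = b)$res)
      ok <- length(sp) > 0 &&
        (length(sp[[1]]) - 2L) <= config$maxIntermediaries
      if (!ok) {
        unconnected <- rbind(unconnected, data.frame(
          a = a, b = b,
          reason = if (length(sp)) "path exceeds intermediary bound"
                   else "no admissible path",
          stringsAsFactors = FALSE))
        next
      }
      tuples <- vapply(sp, function(p) {
        nm <- igraph::V(gAdm)$name[as.integer(p)]
        paste(nm[-c(1L, length(nm))], collapse = "\r")
      }, character(1))
      best <- igraph::V(gAdm)$name[as.integer(sp[[order(tuples)[1L]]])]
      internal <- best[-c(1L, length(best))]
      intermediaries <- union(intermediaries,
                              setdiff(internal, seedsSorted))
      for (k in seq_len(length(best) - 1L))
        addEdge(best[k], best[k + 1L], "intermediary")
    }
  }
  edges <- edges[!duplicated(t(apply(edges[1:2], 1, sort))), , drop = FALSE]
  if (nrow(unconnected))
    logMsg("connectWithIntermediaries: %d seed pair(s) left unconnected",
           nrow(unconnected))
  nodes <- data.frame(
    node = c(seedsSorted, sort(intermediaries)),
    provenance = c(rep("seed", length(seedsSorted)),
                   rep("intermediary", length(intermediaries))),
    stringsAsFactors = FALSE)
  nodes$degree <- unname(deg[nodes$node])
  nodes$degree[is.na(nodes$degree)] <- 0L
  list(nodes = nodes, edges = edges, unconnected = unconnected,
       lowExpressionThreshold = unname(thr))
}

#' Enrich a vertex set with its transcription factors
#'
#' Every TF with at least one target among the current vertices is added
#' (if absent) together with a directed tf-to-target edge; the regulation
#' mode is carried as a provisional sign to be confirmed or overridden by
#' the sign table at assembly.
#'
#' @param vertices current network gene symbols.
#' @param tfTable data.frame with columns tf, target, mode.
#' @param interactome optional igraph used to attach distinct-partner
#'   degrees to the added TFs (for regulator ordering).
#' @return list with `nodes` (data.frame of added TFs) and `edges`
#'   (directed, provenance `"tf_table"`).
#' @export
enrichTranscriptionFactors <- function(vertices, tfTable,
                                       interactome = NULL) {
  hit <- tfTable[tfTable$target %in% vertices, , drop = FALSE]
  newTFs <- sort(setdiff(unique(hit$tf), vertices))
  deg <- if (!is.null(interactome)) distinctDegree(interactome, newTFs)
         else setNames(integer(length(newTFs)), newTFs)
  edges <- data.frame(
    source = hit$tf, target = hit$target, directed = TRUE,
    sign = ifelse(hit$mode == "activation", "activation",
                  ifelse(hit$mode == "repression", "inhibition",
                         NA_character_)),
    provenance = "tf_table", stringsAsFactors = FALSE)
  list(nodes = data.frame(node = newTFs, provenance = "tf_table",
                          degree = unname(deg[newTFs]) %||% integer(0),
                          stringsAsFactors = FALSE),
       edges = edges)
}

#' Assemble a Boolean network from a signed subgraph
#'
#' Expands undirected interactome edges to both directions, resolves the
#' sign of every directed edge (sign table first, then a TF regulation
#' mode if allowed, then the unsigned policy), orders each gene's
#' regulators by descending interactome degree (ties alphabetical),
#' splits them into activators and inhibitors, and builds one nested
#' canalyzing rule per gene. Genes without regulators become frozen
#' inputs holding their value.
#'
#' @param subgraph list with `nodes` (data.frame node, provenance,
#'   degree) and `edges` (data.frame source, target, directed, sign,
#'   provenance), as produced by [connectWithIntermediaries()] and
#'   [enrichTranscriptionFactors()].
#' @param signs sign table data.frame (source, target, sign).
#' @param config a [constructionConfig()].
#' @return list with `network` (a [BooleanNetwork-class]) and `report`
#'   (stage counts and the list of sign fallbacks).
#' @export
assembleNetwork <- function(subgraph, signs,
                            config = constructionConfig()) {
  nodes <- subgraph$nodes
  genes <- nodes$node
  deg <- setNames(nodes$degree %||% rep(0L, nrow(nodes)), genes)
  e <- subgraph$edges
  # undirected edges act in both directions
  und <- e[!e$directed, , drop = FALSE]
  dir <- e[e$directed, , drop = FALSE]
  fwd <- und
  fwd$directed <- rep(TRUE, nrow(und))
  rev <- fwd
  rev$source <- und$target
  rev$target <- und$source
  expanded <- rbind(dir, fwd, rev)
  # later assignment overwrites: keep the last occurrence of each pair
  expanded <- expanded[!duplicated(expanded[c("source", "target")],
                                   fromLast = TRUE), , drop = FALSE]
  signKey <- paste(signs$source, signs$target, sep = "\r")
  signOf <- setNames(signs$sign, signKey)
  key <- paste(expanded$source, expanded$target, sep = "\r")
  resolved <- unname(signOf[key])
  fromTF <- is.na(resolved) & !is.na(expanded$sign) & config$tfModeAsSign
  resolved[fromTF] <- expanded$sign[fromTF]
  unsigned <- is.na(resolved)
  if (any(unsigned)) {
    pairs <- paste0(expanded$source[unsigned], "->",
                    expanded$target[unsigned])
    if (config$unsignedPolicy == "error")
      stop("edge(s) with unresolvable sign: ",
           paste(head(pairs, 10L), collapse = ", "),
           if (sum(unsigned) > 10L) ", ..." else "")
    logMsg("assembleNetwork: defaulting %d unsigned edge(s) to activation",
           sum(unsigned))
    resolved[unsigned] <- "activation"
  }
  expanded$sign <- resolved
  rules <- lapply(genes, function(g) {
    inc <- expanded[expanded$target == g, , drop = FALSE]
    if (!nrow(inc)) return(frozenRule(g))
    regs <- inc$source
    d <- deg[regs]
    d[is.na(d)] <- 0L
    ord <- order(-d, regs)
    inc <- inc[ord, , drop = FALSE]
    buildNCF(g,
             activators = inc$source[inc$sign == "activation"],
             inhibitors = inc$source[inc$sign == "inhibition"],
             scheme = config$ncfScheme)
  })
  edgeDf <- expanded[c("source", "target", "sign", "provenance")]
  rownames(edgeDf) <- NULL
  net <- newBooleanNetwork(genes, rules, edgeDf)
  frozenN <- sum(vapply(rules, function(r) r@meta$type == "frozen",
                        logical(1)))
  list(network = net,
       report = list(nGenes = length(genes), nEdges = nrow(edgeDf),
                     frozenInputs = frozenN,
                     signFallbacks = sum(fromTF),
                     unsignedDefaults = sum(unsigned)))
}

#' Construct a Boolean gene regulatory network from flat-file inputs
#'
#' Runs the full assembly: pathway genes are filtered to those measured in
#' either expression table, reduced to the differentially expressed ones,
#' thinned to interactome hubs, merged with manually curated seed genes,
#' connected through admissible intermediaries, enriched with the
#' transcription factors that regulate them, and signed into nested
#' canalyzing rules. The stages only filter or augment, so the report's
#' stage counts reconstruct the whole decision path.
#'
#' @param pathways named list of pathway gene vectors.
#' @param tumorExpr,controlExpr expression matrices (gene rows); the
#'   tumor table also provides the reference sample for the intermediary
#'   expression check.
#' @param de DE status data.frame (gene, status).
#' @param interactome igraph object.
#' @param tfTable TF regulation data.frame (tf, target, mode).
#' @param signTable sign data.frame (source, target, sign).
#' @param config a [constructionConfig()].
#' @return list with `network` and `report` (per-stage counts, per-pathway
#'   retention, DE split, hub degrees, intermediaries, TFs, unconnected
#'   pairs).
#' @export
constructNetwork <- function(pathways, tumorExpr, controlExpr, de,
                             interactome, tfTable, signTable,
                             config = constructionConfig()) {
  pw <- selectExpressedPathwayGenes(pathways, tumorExpr, controlExpr)
  deRes <- retainDifferential(pw$genes, de)
  hubs <- selectHubs(deRes$genes, interactome, config$minHubDegree)
  seeds <- sort(unique(c(hubs$genes, config$seedGenes)))
  sub <- connectWithIntermediaries(seeds, interactome, tumorExpr, config)
  sub$nodes$provenance[sub$nodes$node %in%
                         setdiff(config$seedGenes, hubs$genes)] <- "manual"
  tf <- enrichTranscriptionFactors(sub$nodes$node, tfTable, interactome)
  sub$nodes <- rbind(sub$nodes, tf$nodes)
  sub$edges <- rbind(sub$edges, tf$edges)
  asm <- assembleNetwork(sub, signTable, config)
  report <- list(
    perPathway = pw$perPathway,
    pathwayRetained = length(pw$genes),
    deRetained = length(deRes$genes),
    deCounts = deRes$counts,
    hubs = length(hubs$genes),
    manualSeeds = length(setdiff(config$seedGenes, hubs$genes)),
    intermediaries = sum(sub$nodes$provenance == "intermediary"),
    tfs = nrow(tf$nodes),
    unconnectedPairs = nrow(sub$unconnected),
    lowExpressionThreshold = sub$lowExpressionThreshold,
    assembly = asm$report)
  list(network = asm$network, report = report)
}
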