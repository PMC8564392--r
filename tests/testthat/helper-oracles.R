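# Independent oracles used across the suite. These deliberately avoid the
# package's own parser/DP/dynamics code paths.

# Evaluate rule text through R's own parser: translate the dialect to an R
# logical expression and eval it with gene values bound in an environment.
naiveEvalRuleText <- function(text, values) {
  expr <- gsub("\\bnot\\b", "!", gsub("\\bor\\b", "||",
               gsub("\\band\\b", "&&", text)))
  env <- list2env(lapply(as.list(values), function(x) as.logical(x)))
  as.integer(eval(parse(text = expr), env))
}

# Exhaustive enumeration of optimal monotone step functions of a sorted
# vector: all C(N-1, j) breakpoint sets for every j, levels = interval
# means, tie -> lexicographically smallest tuple (combn's column order).
bruteStepFunctions <- function(v) {
  N <- length(v)
  segSSE <- function(a, b) {
    seg <- v[a:b]
    sum((seg - mean(seg))^2)
  }
  totalSSE <- function(bp) {
    bounds <- c(0, bp, N)
    sum(vapply(seq_len(length(bounds) - 1L), function(s) {
      segSSE(bounds[s] + 1L, bounds[s + 1L])
    }, numeric(1)))
  }
  lapply(seq.int(N - 2L, 1L), function(j) {
    sets <- combn(N - 1L, j)
    costs <- apply(sets, 2, totalSSE)
    best <- which(costs <= min(costs) + 1e-9)[1]
    list(breakpoints = as.integer(sets[, best]), sse = costs[best])
  })
}

# One synchronous update computed definitionally: every gene's rule
# evaluated with evaluateRule against an untouched copy of the old state.
definitionalStep <- function(net, state) {
  genes <- networkGenes(net)
  frozen <- state
  vapply(networkRules(net), function(r) {
    evaluateRule(r, frozen, genes = genes)
  }, integer(1), USE.NAMES = FALSE)
}

# Brute-force consensus: plain counting per gene over a label matrix.
bruteConsensus <- function(labels, minCellFraction) {
  labels <- labels[rowSums(is.na(labels)) == 0L, , drop = FALSE]
  vapply(seq_len(ncol(labels)), function(j) {
    ft <- mean(labels[, j] == "True")
    ff <- mean(labels[, j] == "False")
    if (ft >= minCellFraction) "True"
    else if (ff >= minCellFraction) "False"
    else "X"
  }, character(1))
}

# All admissible seed-to-seed paths on a toy interactome by exhaustive
# simple-path enumeration; returns the internal tuples of the shortest
# admissible paths, sorted.
enumerateAdmissiblePaths <- function(graph, a, b, admissible, maxInternal) {
  paths <- igraph::all_simple_paths(graph, from = a, to = b)
  ok <- Filter(function(p) {
    nm <- igraph::V(graph)$name[as.integer(p)]
    internal <- nm[-c(1L, length(nm))]
    length(internal) <= maxInternal && all(internal %in% admissible)
  }, paths)
  if (!length(ok)) return(NULL)
  lens <- vapply(ok, length, integer(1))
  short <- ok[lens == min(lens)]
  tuples <- vapply(short, function(p) {
    nm <- igraph::V(graph)$name[as.integer(p)]
    paste(nm[-c(1L, length(nm))], collapse = ",")
  }, character(1))
  sort(tuples)
}

randomState <- function(n) as.integer(runif(n) < 0.5)
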