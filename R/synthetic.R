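# Synthetic-data generators: bimodal expression matrices with known
# component labels, random canalyzing networks, planted fixed points, and
# a hand-built construction fixture — every pipeline input with ground
# truth, so the full analysis runs and is validated without downloads.

#' Default sample/cell-type profile
#'
#' The default simulated study: 549 cells over 14 sample groups from 11
#' patients (two lymph-node samples and one re-biopsy have their own
#' sample ids) spanning four tumor subtypes and five cell types. Group
#' sizes and compositions mirror a published breast-cancer single-cell
#' cohort, so simulated outputs have realistic per-group shapes.
#'
#' @return data.frame with columns `sample_id`, `subtype`, `cell_type`,
#'   `n`.
#' @export
defaultGroupProfile <- function() {
  rows <- list(
    list("BC01", "LumA", c(malignant = 24, stromal = 2)),
    list("BC02", "LumA", c(malignant = 56)),
    list("BC03", "LumB", c(malignant = 25, immune_B = 7, immune_T = 5)),
    list("BC03LN", "LumB", c(malignant = 17, immune_B = 35, immune_T = 3)),
    list("BC04", "HER2", c(malignant = 54, immune_T = 3, myeloid = 2)),
    list("BC05", "HER2", c(malignant = 77)),
    list("BC06", "HER2", c(malignant = 17, stromal = 2, immune_B = 6)),
    list("BC07", "TNBC", c(malignant = 32, stromal = 4, immune_B = 3,
                           immune_T = 4, myeloid = 8)),
    list("BC07LN", "TNBC", c(malignant = 34, immune_B = 19)),
    list("BC08", "TNBC", c(malignant = 17, stromal = 6)),
    list("BC09", "TNBC", c(malignant = 4, stromal = 2, immune_B = 1,
                           immune_T = 7, myeloid = 15)),
    list("BC09Re", "TNBC", c(malignant = 2, stromal = 2, immune_B = 1,
                             immune_T = 20, myeloid = 6)),
    list("BC10", "TNBC", c(malignant = 12, stromal = 2, myeloid = 2)),
    list("BC11", "TNBC", c(malignant = 11)))
  do.call(rbind, lapply(rows, function(r) {
    data.frame(sample_id = r[[1]], subtype = r[[2]],
               cell_type = names(r[[3]]), n = as.integer(r[[3]]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Expression simulation parameters
#'
#' Each gene's expression in each cell is drawn from a two-component
#' log-normal mixture whose components are moment-matched to the stated
#' arithmetic mean and standard deviation (log-normality mimics the
#' positivity and skew of single-cell expression). Which component a cell
#' draws from is governed by the gene's per-group high-state probability;
#' dropout is zero-inflation applied after sampling, with the true
#' component label recorded beforehand.
#'
#' @param nGenes number of genes (default 103, the default network size).
#' @param groupProfile data.frame as [defaultGroupProfile()].
#' @param lowMean,highMean component means on the expression scale
#'   (defaults 2 and 8).
#' @param sd component standard deviation on the expression scale
#'   (default 0.5, well-separated components).
#' @param highProb per-gene, per-group probability of the high component:
#'   a matrix (genes x groups), a scalar, or `NULL` to draw uniform
#'   probabilities per gene and group.
#' @param dropoutRate probability a sampled value is zeroed (default
#'   0.05).
#' @return list of class `ExpressionSimParams`.
#' @export
expressionSimParams <- function(nGenes = 103L,
                                groupProfile = defaultGroupProfile(),
                                lowMean = 2, highMean = 8, sd = 0.5,
                                highProb = NULL, dropoutRate = 0.05) {
  stopifnot(lowMean >= 0, lowMean < highMean, sd > 0,
            dropoutRate >= 0, dropoutRate <= 1,
            all(groupProfile$n >= 1L))
  structure(list(nGenes = as.integer(nGenes), groupProfile = groupProfile,
                 lowMean = lowMean, highMean = highMean, sd = sd,
                 highProb = highProb, dropoutRate = dropoutRate),
            class = "ExpressionSimParams")
}

# log-normal parameters matching arithmetic mean m and sd s
.lnormPar <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a bimodal genes-by-cells expression matrix
#'
#' Draws every gene-by-cell value from the low or high mixture component
#' according to the gene's per-group high-state probability, records the
#' true component label, applies dropout, and emits the cell annotation
#' table matching the group profile. Reproducible: the same `(params,
#' seed)` pair yields an identical result.
#'
#' @param params an [expressionSimParams()].
#' @param seed integer seed.
#' @return list with `expr` (matrix, genes x cells), `annotations`
#'   (data.frame cell_id, sample_id, subtype, cell_type, pooled),
#'   `truth` (0/1 matrix of true component labels), and `params`.
#' @export
simulateExpressionMatrix <- function(params = expressionSimParams(),
                                     seed = 1L) {
  stopifnot(inherits(params, "ExpressionSimParams"))
  prof <- params$groupProfile
  nCells <- sum(prof$n)
  nGenes <- params$nGenes
  groups <- paste(prof$sample_id, prof$cell_type, sep = "|")
  withSeed(seed, {
    hp <- params$highProb
    if (is.null(hp)) {
      hp <- matrix(runif(nGenes * nrow(prof)), nGenes, nrow(prof))
    } else if (length(hp) == 1L) {
      hp <- matrix(hp, nGenes, nrow(prof))
    }
    stopifnot(nrow(hp) == nGenes, ncol(hp) == nrow(prof),
              all(hp >= 0 & hp <= 1))
    colnames(hp) <- groups
    lo <- .lnormPar(max(params$lowMean, 1e-8), params$sd)
    hi <- .lnormPar(params$highMean, params$sd)
    geneNames <- sprintf("G%03d", seq_len(nGenes))
    expr <- matrix(0, nGenes, nCells)
    truth <- matrix(0L, nGenes, nCells)
    ann <- data.frame(cell_id = character(nCells),
                      sample_id = character(nCells),
                      subtype = character(nCells),
                      cell_type = character(nCells),
                      pooled = logical(nCells), stringsAsFactors = FALSE)
    col <- 0L
    counter <- integer(0)
    for (g in seq_len(nrow(prof))) {
      sid <- prof$sample_id[g]
      for (k in seq_len(prof$n[g])) {
        col <- col + 1L
        counter[sid] <- (counter[sid] %||% 0L) + 1L
        if (is.na(counter[sid])) counter[sid] <- 1L
        ann$cell_id[col] <- sprintf("%s_c%03d", sid, counter[[sid]])
        ann$sample_id[col] <- sid
        ann$subtype[col] <- prof$subtype[g]
        ann$cell_type[col] <- prof$cell_type[g]
        high <- runif(nGenes) < hp[, g]
        truth[, col] <- as.integer(high)
        vals <- numeric(nGenes)
        vals[high] <- rlnorm(sum(high), hi$meanlog, hi$sdlog)
        vals[!high] <- rlnorm(sum(!high), lo$meanlog, lo$sdlog)
        if (params$dropoutRate > 0)
          vals[runif(nGenes) < params$dropoutRate] <- 0
        expr[, col] <- vals
      }
    }
    dimnames(expr) <- list(geneNames, ann$cell_id)
    dimnames(truth) <- dimnames(expr)
    list(expr = expr, annotations = ann, truth = truth, params = params)
  })
}

#' Generate a random nested canalyzing network
#'
#' Each gene receives a Poisson-distributed number (at least 1) of
#' regulators sampled without replacement, each independently an
#' activator or inhibitor, and its rule is built with [buildNCF()] under
#' the inhibitor-dominant scheme. The same seed yields a byte-identical
#' rule file.
#'
#' @param n number of genes.
#' @param meanInDegree mean regulator count (default 2).
#' @param seed integer seed.
#' @return a [BooleanNetwork-class] with a populated signed edge list.
#' @export
randomNCFNetwork <- function(n, meanInDegree = 2, seed = 1L) {
  stopifnot(n >= 1L)
  withSeed(seed, {
    genes <- sprintf("G%03d", seq_len(n))
    rules <- vector("list", n)
    edges <- list()
    for (i in seq_len(n)) {
      k <- min(max(rpois(1L, meanInDegree), 1L), n)
      regs <- sample(genes, k)
      act <- runif(k) < 0.5
      rules[[i]] <- buildNCF(genes[i],
                             activators = regs[act],
                             inhibitors = regs[!act])
      edges[[i]] <- data.frame(
        source = regs, target = genes[i],
        sign = ifelse(act, "activation", "inhibition"),
        provenance = "manual", stringsAsFactors = FALSE)
    }
    newBooleanNetwork(genes, rules, do.call(rbind, edges))
  })
}

#' Planted-network specification
#'
#' @param nGenes network size (default 103).
#' @param nInputs number of frozen input genes (default 15% of genes,
#'   at least 2).
#' @param targetState optional 0/1 vector of length `nGenes` to plant;
#'   `NULL` draws one (with both input values represented, so the
#'   construction is feasible).
#' @param seed integer seed.
#' @return list of class `PlantedNetworkSpec`.
#' @export
plantedNetworkSpec <- function(nGenes = 103L, nInputs = NULL,
                               targetState = NULL, seed = 1L) {
  nInputs <- nInputs %||% max(2L, round(0.15 * nGenes))
  stopifnot(nInputs >= 1L, nInputs <= nGenes)
  structure(list(nGenes = as.integer(nGenes), nInputs = as.integer(nInputs),
                 targetState = targetState, seed = seed),
            class = "PlantedNetworkSpec")
}

#' Plant a fixed-point attractor in a Boolean network
#'
#' Builds a network in which a chosen target state is provably a fixed
#' point of the synchronous dynamics: the first `nInputs` genes are
#' frozen inputs held at their target values, and every other gene is
#' regulated only by inputs, with activators/inhibitors chosen so its
#' inhibitor-dominant rule evaluates to its target value when the inputs
#' sit at theirs. Because non-input genes depend on inputs alone, every
#' state agreeing with the target on the inputs reaches the planted fixed
#' point in one step — the basin is known by construction. The planted
#' state is verified with one synchronous update before returning.
#'
#' @param spec a [plantedNetworkSpec()].
#' @return list with `network`, `attractor` (the planted singleton),
#'   `targetState`, `inputGenes`, and `constantGenes` (ground-truth
#'   constant genes: all of them, with their planted values).
#' @export
plantFixedPoint <- function(spec = plantedNetworkSpec()) {
  stopifnot(inherits(spec, "PlantedNetworkSpec"))
  n <- spec$nGenes
  nIn <- spec$nInputs
  withSeed(spec$seed, {
    genes <- sprintf("G%03d", seq_len(n))
    target <- spec$targetState
    if (is.null(target)) {
      target <- as.integer(runif(n) < 0.5)
      if (nIn >= 2L) {       # make both input values available
        target[1L] <- 1L
        target[2L] <- 0L
      }
    }
    target <- as.integer(target)
    stopifnot(length(target) == n, all(target %in% 0:1))
    inputs <- genes[seq_len(nIn)]
    onIn <- inputs[target[seq_len(nIn)] == 1L]
    offIn <- inputs[target[seq_len(nIn)] == 0L]
    rules <- vector("list", n)
    for (i in seq_len(nIn)) rules[[i]] <- frozenRule(genes[i])
    for (i in seq.int(nIn + 1L, length.out = n - nIn)) {
      if (target[i] == 1L) {
        if (!length(onIn))
          stop("infeasible spec: a target-1 gene needs an active input")
        act <- sample(onIn, sample.int(min(3L, length(onIn)), 1L))
        inh <- if (length(offIn))
          sample(offIn, sample.int(min(2L, length(offIn)) + 1L, 1L) - 1L)
        else character()
      } else {
        if (length(onIn)) {
          inh <- sample(onIn, sample.int(min(2L, length(onIn)), 1L))
          act <- if (length(offIn))
            sample(offIn, sample.int(min(2L, length(offIn)) + 1L, 1L) - 1L)
          else character()
        } else if (length(offIn)) {
          act <- sample(offIn, sample.int(min(2L, length(offIn)), 1L))
          inh <- character()
        } else stop("infeasible spec: no inputs to regulate with")
      }
      rules[[i]] <- buildNCF(genes[i], activators = act, inhibitors = inh)
    }
    net <- newBooleanNetwork(genes, rules)
    if (!identical(synchronousStep(net, target), target))
      stop("internal error: planted state is not a fixed point")
    list(network = net,
         attractor = canonicalAttractor(list(target)),
         targetState = target,
         inputGenes = inputs,
         constantGenes = setNames(target, genes))
  })
}

#' Hand-built construction fixture with known ground truth
#'
#' A small, fully deterministic input set for the network-construction
#' stages: two pathway lists with some unmeasured genes, tumor/control
#' expression tables, a DE status table, an interactome whose designated
#' hub genes sit exactly around the degree-50 boundary, intermediary
#' candidates on short connecting paths (one of them below the
#' low-expression threshold), a TF table with one off-network TF, and a
#' sign table covering every interactome-derived edge. The returned
#' `groundTruth` element states the expected outcome of every stage so
#' tests can recompute them independently.
#'
#' @return list with `pathways`, `tumorExpr`, `controlExpr`, `de`,
#'   `interactome`, `tfTable`, `signTable`, `config`, `groundTruth`.
#' @export
syntheticConstructionInputs <- function() {
  pathways <- list(
    APOPT_LIKE = c(sprintf("P%02d", 1:20), sprintf("X%02d", 1:10)),
    GROWTH_LIKE = c(sprintf("P%02d", 15:30), sprintf("Y%02d", 1:5)))
  measured <- c(sprintf("P%02d", 1:30), sprintf("I%d", 1:4), "M1")
  mk <- function(vals) {
    m <- matrix(vals, nrow = length(measured), ncol = 2,
                dimnames = list(measured, c("tumor_line", "replicate")))
    m
  }
  tumorExpr <- mk(5)
  tumorExpr["I4", ] <- 0.5          # below the low-expression threshold
  controlExpr <- mk(4)
  de <- data.frame(
    gene = sprintf("P%02d", 1:30),
    status = ifelse(sprintf("P%02d", 1:30) %in%
                      c("P01", "P03", "P05", "P07", "P09"),
                    c("up", "down")[1 + (1:30 %% 2)], "ns"),
    stringsAsFactors = FALSE)
  # interactome: hub candidates with filler partners around the boundary
  filler <- function(g, k) data.frame(a = g, b = sprintf("F_%s_%02d", g, 1:k),
                                      stringsAsFactors = FALSE)
  backbone <- data.frame(
    a = c("P01", "P01", "I1", "P03", "I2", "I3", "M1", "I4"),
    b = c("P03", "I1", "P05", "I2", "I3", "P05", "I4", "P01"),
    stringsAsFactors = FALSE)
  el <- rbind(backbone,
              filler("P01", 57), filler("P03", 53), filler("P05", 48),
              filler("P07", 49))
  interactome <- igraph::graph_from_data_frame(el, directed = FALSE)
  tfTable <- data.frame(
    tf = c("T1", "T2", "T3"),
    target = c("P01", "I1", "Z99"),
    mode = c("activation", "repression", "activation"),
    stringsAsFactors = FALSE)
  core <- backbone[backbone$a != "M1" & backbone$a != "I4" &
                     backbone$b != "I4", ]
  und <- rbind(setNames(core, c("source", "target")),
               setNames(core[c("b", "a")], c("source", "target")))
  signTable <- data.frame(
    source = und$source, target = und$target,
    sign = ifelse(und$source %in% c("I1", "I2", "I3"),
                  "inhibition", "activation"),
    stringsAsFactors = FALSE)
  config <- constructionConfig(minHubDegree = 50L, maxIntermediaries = 3L,
                               lowExpressionThreshold = 1.0,
                               referenceSample = "tumor_line",
                               seedGenes = "M1")
  groundTruth <- list(
    retainedPerPathway = c(APOPT_LIKE = 20L, GROWTH_LIKE = 16L),
    pathwayGenes = sprintf("P%02d", 1:30),
    deRetained = c("P01", "P03", "P05", "P07", "P09"),
    hubs = c("P01", "P03", "P05"),   # degrees 60, 55, 50; P07 has 49
    hubDegrees = c(P01 = 60L, P03 = 55L, P05 = 50L, P07 = 49L, P09 = 0L),
    seeds = c("M1", "P01", "P03", "P05"),
    intermediaries = c("I1", "I2", "I3"),
    unconnectedPairs = 3L,           # M1 only reaches P01 through low I4
    tfs = c("T1", "T2"),
    nGenes = 9L)
  list(pathways = pathways, tumorExpr = tumorExpr,
       controlExpr = controlExpr, de = de, interactome = interactome,
       tfTable = tfTable, signTable = signTable, config = config,
       groundTruth = groundTruth)
}

#' Write the standard input files for a simulated study
#'
#' Serializes a [simulateExpressionMatrix()] result (and optionally a
#' network rule file) in the exact flat-file formats the pipeline reads,
#' plus a ground-truth JSON.
#'
#' @param sim result of [simulateExpressionMatrix()].
#' @param dir output directory (created if needed).
#' @param network optional [BooleanNetwork-class] to write as
#'   `rules.txt`.
#' @return named vector of written paths, invisibly.
#' @export
writeSimulatedStudy <- function(sim, dir, network = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(sim$expr, paths["expression"], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(sim$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(truth = sim$truth,
         groupProfile = sim$params$groupProfile),
    paths["truth"], matrix = "rowmajor")
  if (!is.null(network)) {
    paths["rules"] <- file.path(dir, "rules.txt")
    writeRules(network, paths["rules"])
  }
  invisible(paths)
}
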