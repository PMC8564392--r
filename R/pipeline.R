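# End-to-end orchestration: network (from a rule file or constructed from
# flat tables) -> per-scope binarization -> per-cell attractor search ->
# grouping and consensus -> cross-group summaries, with every stage's
# parameters and counts logged and written under one run directory.

#' Pipeline configuration
#'
#' Builds the configuration [runPipeline()] consumes. Inputs may be given
#' as file paths (read with the package's readers) or as in-memory
#' objects. Exactly one of `ruleFile`/`network` or the construction
#' inputs must identify the network.
#'
#' @param expression expression TSV path or genes-by-cells matrix.
#' @param annotations annotation TSV path or data.frame.
#' @param ruleFile optional rule-file path (skips construction).
#' @param network optional [BooleanNetwork-class] (skips construction).
#' @param construction optional named list with elements `pathways`,
#'   `tumorExpr`, `controlExpr`, `de`, `interactome`, `tfTable`,
#'   `signTable` (paths or objects).
#' @param constructionConfig a [constructionConfig()]; `NULL` uses the
#'   defaults.
#' @param binarizationScope `"per_sample"` (each sample's cells are
#'   thresholded jointly, the default) or `"global"` (all cells at once).
#' @param maxSteps attractor search step budget (default 10000, logged so
#'   no-result rates are reproducible).
#' @param cycleFraction per-cycle constancy fraction for gene labels
#'   (default 1: strictly constant over the cycle).
#' @param minCellFraction consensus cell fraction (default 0.95,
#'   boundary inclusive).
#' @param malignantOnly restrict the cross-group summary to malignant
#'   groups (default TRUE).
#' @param outputDir run directory for all written artifacts.
#' @param seed integer recorded in the run metadata (the pipeline stages
#'   are deterministic; the seed matters when the config also asks for
#'   simulated inputs upstream).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(expression, annotations,
                           ruleFile = NULL, network = NULL,
                           construction = NULL,
                           constructionConfig = NULL,
                           binarizationScope = c("per_sample", "global"),
                           maxSteps = 10000L,
                           cycleFraction = 1,
                           minCellFraction = 0.95,
                           malignantOnly = TRUE,
                           outputDir = "attractome_run",
                           seed = 1L) {
  if (is.null(ruleFile) && is.null(network) && is.null(construction))
    stop("config error: provide ruleFile, network, or construction inputs")
  stopifnot(maxSteps >= 1L, cycleFraction > 0.5, cycleFraction <= 1,
            minCellFraction > 0.5, minCellFraction <= 1)
  structure(list(expression = expression, annotations = annotations,
                 ruleFile = ruleFile, network = network,
                 construction = construction,
                 constructionConfig = constructionConfig,
                 binarizationScope = match.arg(binarizationScope),
                 maxSteps = as.integer(maxSteps),
                 cycleFraction = cycleFraction,
                 minCellFraction = minCellFraction,
                 malignantOnly = isTRUE(malignantOnly),
                 outputDir = outputDir, seed = as.integer(seed)),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipelineConfig()]
#'   arguments (input values are interpreted as file paths).
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipelineConfig, y)
}

.loadNetwork <- function(config) {
  if (!is.null(config$network)) return(list(network = config$network,
                                            report = NULL))
  if (!is.null(config$ruleFile)) {
    logMsg("stage network: loading rule file %s", config$ruleFile)
    return(list(network = parseRules(readLines(config$ruleFile)),
                report = NULL))
  }
  cx <- config$construction
  logMsg("stage network: constructing from flat tables")
  asObj <- function(x, reader) if (is.character(x) && length(x) == 1L &&
                                     file.exists(x)) reader(x) else x
  constructNetwork(
    pathways = asObj(cx$pathways, readPathwayLists),
    tumorExpr = asObj(cx$tumorExpr, readExpressionTable),
    controlExpr = asObj(cx$controlExpr, readExpressionTable),
    de = asObj(cx$de, readDEStatusTable),
    interactome = asObj(cx$interactome, readInteractome),
    tfTable = asObj(cx$tfTable, readTFTable),
    signTable = asObj(cx$signTable, readSignTable),
    config = config$constructionConfig %||% constructionConfig())
}

.binarizeScoped <- function(expr, ann, scope) {
  if (scope == "global") {
    bin <- binarizeMatrix(expr)
    thr <- cbind(scope = "global", bin$thresholds)
    return(list(bits = bin$bits, thresholds = thr))
  }
  bitsList <- list()
  thrList <- list()
  for (sid in unique(ann$sample_id)) {
    cells <- ann$cell_id[ann$sample_id == sid]
    bin <- binarizeMatrix(expr[, cells, drop = FALSE])
    bitsList[[sid]] <- bin$bits
    thrList[[sid]] <- cbind(scope = sid, bin$thresholds)
  }
  bits <- do.call(cbind, bitsList)
  list(bits = bits[, ann$cell_id, drop = FALSE],
       thresholds = do.call(rbind, thrList))
}

#' Run the full attractor pipeline
#'
#' Executes every stage in order: network load or construction,
#' binarization of the expression of the network genes (per sample by
#' default), per-cell synchronous trajectory simulation to an attractor,
#' per-cell gene constancy labels, per-(sample, cell type) consensus
#' calls, and the cross-group constancy summary. All artifacts are
#' written under `config$outputDir` with a JSON report and manifest;
#' identical config yields byte-identical outputs.
#'
#' @param config a [pipelineConfig()] or the path to its YAML form.
#' @return (invisibly) list with `network`, `bits`, `thresholds`,
#'   `attractors` (per-cell data.frame), `labels`, `consensus` (per-group
#'   tables), `summary`, `report`, and `files`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  stopifnot(inherits(config, "PipelineConfig"))
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name, code) {
    s <- proc.time()[["elapsed"]]
    r <- tryCatch(code, error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    logMsg("stage %s done in %.1fs", name, proc.time()[["elapsed"]] - s)
    r
  }

  netRes <- stage("network", .loadNetwork(config))
  net <- netRes$network
  genes <- networkGenes(net)

  inputs <- stage("inputs", {
    expr <- config$expression
    if (is.character(expr)) expr <- readExpressionTable(expr)
    ann <- config$annotations
    if (is.character(ann)) ann <- readCellAnnotations(ann)
    missing <- setdiff(genes, rownames(expr))
    if (length(missing))
      stop("expression table lacks network gene(s): ",
           paste(head(missing, 10L), collapse = ", "))
    ann <- groupCells(ann)
    list(expr = as.matrix(expr)[genes, ann$cell_id, drop = FALSE],
         ann = ann)
  })
  ann <- inputs$ann

  bin <- stage("binarization",
               .binarizeScoped(inputs$expr, ann, config$binarizationScope))

  dyn <- stage("attractors", {
    cache <- new.env(parent = emptyenv())
    n <- nrow(ann)
    rows <- vector("list", n)
    labels <- matrix(NA_character_, n, length(genes),
                     dimnames = list(ann$cell_id, genes))
    attrs <- vector("list", n)
    for (i in seq_len(n)) {
      tr <- simulateToAttractor(net, bin$bits[, ann$cell_id[i]],
                                maxSteps = config$maxSteps, cache = cache)
      a <- trajectoryAttractor(tr)
      attrs[[i]] <- a
      rows[[i]] <- data.frame(
        cell_id = ann$cell_id[i], sample_id = ann$sample_id[i],
        cell_type = ann$cell_type[i], group = ann$group[i],
        steps_to_cycle = if (is.null(a)) NA_integer_
                         else tr@firstRepeatIndex - 1L,
        period = if (is.null(a)) NA_integer_ else a@period,
        kind = if (is.null(a)) "no_result" else a@kind,
        attractor = if (is.null(a)) NA_character_ else attractorKey(a),
        stringsAsFactors = FALSE)
      if (!is.null(a))
        labels[i, ] <- labelAttractorGenes(a, config$cycleFraction)
    }
    list(table = do.call(rbind, rows), labels = labels, attractors = attrs)
  })

  consensus <- stage("consensus", {
    out <- list()
    for (g in unique(ann$group)) {
      rows <- ann$group == g
      lab <- dyn$labels[rows, , drop = FALSE]
      if (all(is.na(lab[, 1]))) {
        warning("group '", g, "' has no attractor-bearing cell; skipped")
        next
      }
      out[[g]] <- consensusGenes(lab, config$minCellFraction)
    }
    out
  })

  summary <- stage("summary", {
    keep <- names(consensus)
    if (config$malignantOnly) {
      mal <- keep[endsWith(keep, "|malignant")]
      if (length(mal)) keep <- mal
      else logMsg("summary: no malignant group; summarizing all groups")
    }
    subtypes <- NULL
    if (!is.null(ann$subtype)) {
      map <- unique(ann[c("group", "subtype")])
      subtypes <- setNames(map$subtype, map$group)
    }
    summarizeAcrossGroups(consensus[keep], panel = genes,
                          subtypes = subtypes)
  })

  report <- list(
    config = list(binarizationScope = config$binarizationScope,
                  maxSteps = config$maxSteps,
                  cycleFraction = config$cycleFraction,
                  minCellFraction = config$minCellFraction,
                  malignantOnly = config$malignantOnly,
                  seed = config$seed),
    network = list(nGenes = length(genes),
                   nEdges = nrow(networkEdges(net)),
                   construction = netRes$report),
    cells = list(total = nrow(ann),
                 groups = as.list(attr(ann, "groupSizes"))),
    samples = lapply(split(dyn$table, dyn$table$sample_id), function(d) {
      tt <- table(ifelse(d$kind == "no_result", "no_result", d$cell_type))
      fr <- as.list(100 * as.numeric(tt) / nrow(d))
      names(fr) <- names(tt)
      list(nCells = nrow(d), attractorPercent = fr)
    }),
    consensus = lapply(consensus, function(tab) {
      list(nCells = attr(tab, "nCells"), nNoResult = attr(tab, "nNoResult"),
           constantTrue = sum(tab$label == "True"),
           constantFalse = sum(tab$label == "False"))
    }))

  files <- stage("write", {
    dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(x) file.path(config$outputDir, x)
    writeRules(net, fp("rules.txt"))
    networkToJSON(net, fp("network.json"))
    writeBinarization(bin, fp("binarized.tsv"), fp("thresholds.csv"))
    utils::write.csv(dyn$table, fp("attractors.csv"), row.names = FALSE)
    consDf <- do.call(rbind, lapply(names(consensus), function(g) {
      cbind(group = g, consensus[[g]])
    }))
    utils::write.csv(consDf, fp("consensus.csv"), row.names = FALSE)
    utils::write.csv(as.data.frame(summary$matrix), fp("summary_matrix.csv"))
    jsonlite::write_json(report, fp("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out <- c("rules.txt", "network.json", "binarized.tsv", "thresholds.csv",
             "attractors.csv", "consensus.csv", "summary_matrix.csv",
             "report.json")
    writeLines(out, fp("MANIFEST"))
    vapply(c(out, "MANIFEST"), fp, character(1))
  })
  logMsg("pipeline done in %.1fs", proc.time()[["elapsed"]] - t0)
  invisible(list(network = net, bits = bin$bits,
                 thresholds = bin$thresholds,
                 attractors = dyn$table, labels = dyn$labels,
                 consensus = consensus, summary = summary,
                 report = report, files = files))
}
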