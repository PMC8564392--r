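# Gene-level reading of attractors: per-attractor constancy labels
# (True/False/X), grouping of cells by (sample, cell type), and the
# >= 95%-of-cells consensus call per group.

.cellTypes <- c("malignant", "stromal", "immune_B", "immune_T", "myeloid",
                "other")

#' Constancy label of one gene in an attractor
#'
#' Computes the fraction of cycle states in which the gene is on. The gene
#' is labeled `"True"` if that fraction is at least `cycleFraction`,
#' `"False"` if the off-fraction is at least `cycleFraction`, and `"X"`
#' (varying) otherwise. The default `cycleFraction = 1` demands strict
#' constancy over the whole cycle; values such as 0.8 give a documented
#' "most states of the cycle" reading.
#'
#' @param attr an [Attractor-class].
#' @param geneIndex 1-based gene position in the network ordering.
#' @param cycleFraction required fraction of cycle states, in (0.5, 1].
#' @return list with `label` (`"True"`, `"False"` or `"X"`) and
#'   `fraction` (fraction of cycle states with the gene on).
#' @export
labelGeneConstancy <- function(attr, geneIndex, cycleFraction = 1) {
  stopifnot(cycleFraction > 0.5, cycleFraction <= 1)
  bits <- vapply(attr@states, `[`, integer(1), geneIndex)
  frac <- mean(bits)
  label <- if (frac >= cycleFraction) "True"
           else if ((1 - frac) >= cycleFraction) "False"
           else "X"
  list(label = label, fraction = frac)
}

# All genes of one attractor at once; returns a character vector.
labelAttractorGenes <- function(attr, cycleFraction = 1) {
  stopifnot(cycleFraction > 0.5, cycleFraction <= 1)
  m <- do.call(rbind, attr@states)
  frac <- colMeans(m)
  ifelse(frac >= cycleFraction, "True",
         ifelse((1 - frac) >= cycleFraction, "False", "X"))
}

#' Group cells by sample and cell type
#'
#' Partitions the annotated cells into analysis groups keyed
#' `(sample_id, cell_type)`, dropping pooled cells (bulk profiles mixed
#' into single-cell accessions) first. Lymph-node and re-biopsy samples
#' carry their own sample ids and therefore form their own groups.
#'
#' @param annotations data.frame with columns `cell_id`, `sample_id`,
#'   `cell_type`, and optionally `pooled` (logical) and `subtype`.
#' @return data.frame of retained cells with an added `group` column
#'   (`"sample|cell_type"`); group sizes are in `attr(, "groupSizes")`.
#' @export
groupCells <- function(annotations) {
  required <- c("cell_id", "sample_id", "cell_type")
  miss <- setdiff(required, names(annotations))
  if (length(miss))
    stop("annotation table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(annotations$cell_id))
    stop("cell ids must be unique")
  bad <- is.na(annotations$sample_id) | !nzchar(annotations$sample_id)
  if (any(bad))
    stop("cell(s) with unknown sample id: ",
         paste(head(annotations$cell_id[bad], 5L), collapse = ", "))
  if (!is.null(annotations$pooled)) {
    dropped <- sum(annotations$pooled)
    if (dropped) logMsg("groupCells: excluding %d pooled cell(s)", dropped)
    annotations <- annotations[!annotations$pooled, , drop = FALSE]
  }
  annotations$group <- paste(annotations$sample_id, annotations$cell_type,
                             sep = "|")
  sizes <- table(annotations$group)
  attr(annotations, "groupSizes") <-
    setNames(as.integer(sizes), names(sizes))
  annotations
}

#' Group-level consensus gene calls
#'
#' Given the per-cell constancy labels of one group, a gene receives the
#' consensus call `"True"` (respectively `"False"`) when at least
#' `minCellFraction` of the group's attractor-bearing cells carry that
#' label; otherwise it is a no-call (`"X"`). The boundary is inclusive:
#' 19 of 20 cells is exactly 95% and makes the call at the default
#' threshold. Cells without an attractor (no-result trajectories) are
#' excluded from the denominator and their count reported.
#'
#' @param labels character matrix, cells in rows, genes in columns, values
#'   in `True/False/X`; rows for no-result cells may be `NA` and are
#'   dropped.
#' @param minCellFraction required fraction of cells, default 0.95.
#' @return data.frame with columns `gene`, `label` (`True/False/X`),
#'   `supportFraction` (fraction of attractor-bearing cells carrying the
#'   winning constant label; for no-calls, the larger of the two), and
#'   attributes `nCells` and `nNoResult`.
#' @export
consensusGenes <- function(labels, minCellFraction = 0.95) {
  stopifnot(minCellFraction > 0.5, minCellFraction <= 1)
  labels <- as.matrix(labels)
  ok <- rowSums(is.na(labels)) == 0L
  nNoResult <- sum(!ok)
  labels <- labels[ok, , drop = FALSE]
  if (!nrow(labels))
    stop("group is empty after excluding no-result cells")
  genes <- colnames(labels) %||% paste0("g", seq_len(ncol(labels)))
  fracTrue <- colMeans(labels == "True")
  fracFalse <- colMeans(labels == "False")
  call <- ifelse(fracTrue >= minCellFraction, "True",
                 ifelse(fracFalse >= minCellFraction, "False", "X"))
  support <- ifelse(call == "True", fracTrue,
                    ifelse(call == "False", fracFalse,
                           pmax(fracTrue, fracFalse)))
  out <- data.frame(gene = genes, label = call,
                    supportFraction = support,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "nCells") <- nrow(labels)
  attr(out, "nNoResult") <- nNoResult
  out
}

#' Summarize consensus calls across groups
#'
#' Builds the genes-by-groups constancy matrix over
#' `{constant_true, constant_false, non_constant}` for a gene panel, and
#' derives cross-group expression patterns ("expressed in all groups
#' except ...", "never expressed in subtype ..."). Groups are ordered by
#' subtype (when given) and then by name, the layout used to compare
#' patients within and across tumor subtypes.
#'
#' @param consensusTables named list of [consensusGenes()] outputs, one
#'   per group.
#' @param panel gene symbols to report; every panel gene must appear in
#'   all consensus tables.
#' @param subtypes optional named character vector mapping group names to
#'   tumor subtype labels (e.g., LumA/LumB/HER2/TNBC).
#' @return list with `matrix` (character matrix, genes x groups) and
#'   `patterns` (per-gene list: groups constant-on, constant-off,
#'   non-constant, plus pattern notes).
#' @export
summarizeAcrossGroups <- function(consensusTables, panel, subtypes = NULL) {
  stopifnot(length(consensusTables) >= 1L)
  groups <- names(consensusTables)
  if (is.null(groups)) stop("consensusTables must be named by group")
  if (!is.null(subtypes))
    groups <- groups[order(match(subtypes[groups], unique(subtypes)), groups)]
  for (g in groups) {
    missing <- setdiff(panel, consensusTables[[g]]$gene)
    if (length(missing))
      stop("gene(s) absent from the network consensus for group '", g,
           "': ", paste(missing, collapse = ", "))
  }
  m <- matrix("non_constant", nrow = length(panel), ncol = length(groups),
              dimnames = list(panel, groups))
  for (g in groups) {
    tab <- consensusTables[[g]]
    lab <- setNames(tab$label, tab$gene)[panel]
    m[, g] <- ifelse(lab == "True", "constant_true",
                     ifelse(lab == "False", "constant_false",
                            "non_constant"))
  }
  patterns <- lapply(panel, function(gene) {
    on <- groups[m[gene, ] == "constant_true"]
    off <- groups[m[gene, ] == "constant_false"]
    varying <- groups[m[gene, ] == "non_constant"]
    notes <- character()
    if (length(on) == length(groups)) {
      notes <- c(notes, "expressed in all groups")
    } else if (length(on) >= length(groups) - 2L && length(on) > 0L) {
      notes <- c(notes, paste0("expressed in all groups except ",
                               paste(setdiff(groups, on), collapse = ", ")))
    }
    if (!is.null(subtypes)) {
      for (st in unique(subtypes[groups])) {
        gst <- groups[subtypes[groups] == st]
        if (length(gst) && all(m[gene, gst] == "constant_false"))
          notes <- c(notes,
                     paste0("never expressed in subtype ", st))
      }
    }
    list(constant_true = on, constant_false = off,
         non_constant = varying, notes = notes)
  })
  names(patterns) <- panel
  list(matrix = m, patterns = patterns)
}
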