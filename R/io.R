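# Readers for the flat-file inputs: expression and annotation TSVs,
# pathway gene lists (plain or GMT), DE status tables, interactomes
# (PSI-MITAB 2.5 or 2-column TSV), TF regulation and sign tables.

#' Read a genes-by-cells expression table
#'
#' Tab-separated, genes in rows (first column or row names), cells in
#' columns, non-negative real values.
#'
#' @param path TSV path.
#' @return numeric matrix with gene row names and cell column names.
#' @export
readExpressionTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[1]])) {
    rn <- df[[1]]
    df <- df[-1]
  } else {
    rn <- rownames(df)
  }
  m <- as.matrix(df)
  rownames(m) <- rn
  if (anyDuplicated(rn)) stop("duplicate gene identifiers in ", path)
  if (any(m < 0)) stop("negative expression values in ", path)
  m
}

#' Read a cell annotation table
#'
#' Tab-separated with columns `cell_id`, `sample_id`, `cell_type`, and
#' optionally `pooled` (logical) and `subtype`.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readCellAnnotations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("cell_id", "sample_id", "cell_type"), names(df))
  if (length(miss))
    stop("annotation table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(df$pooled)) df$pooled <- as.logical(df$pooled)
  df
}

#' Read pathway gene lists
#'
#' Accepts plain-text lists (one symbol per line, one file per pathway,
#' named by file) or a single GMT file (pathway name, description, then
#' genes, tab-separated).
#'
#' @param paths character vector of plain-list paths, or one `.gmt` path.
#' @param names optional pathway names for plain lists; defaults to file
#'   base names.
#' @return named list of character vectors.
#' @export
readPathwayLists <- function(paths, names = NULL) {
  if (length(paths) == 1L && grepl("\\.gmt$", paths, ignore.case = TRUE)) {
    lines <- readLines(paths)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    out <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
    names(out) <- vapply(parts, `[`, character(1), 1L)
    return(out)
  }
  out <- lapply(paths, function(p) {
    g <- trimws(readLines(p))
    unique(g[nzchar(g) & !startsWith(g, "#")])
  })
  names(out) <- names %||% sub("\\.[^.]*$", "", basename(paths))
  out
}

#' Read a differential-expression status table
#'
#' Tab-separated with columns `gene` and `status` in `{up, down, ns}`.
#'
#' @param path TSV path.
#' @return data.frame with one row per gene.
#' @export
readDEStatusTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene", "status"), names(df))
  if (length(miss))
    stop("DE table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$status), c("up", "down", "ns"))
  if (length(bad))
    stop("DE status values must be up/down/ns; found: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(df$gene)) stop("DE table has duplicate gene rows")
  df
}

# Pull a gene symbol out of a PSI-MITAB alias field, falling back to the
# bare identifier with its database prefix stripped.
.mitabSymbol <- function(alias, id) {
  m <- regmatches(alias, regexec("([A-Za-z0-9_.-]+)\\(gene name\\)", alias))[[1]]
  if (length(m) == 2L) return(m[2])
  m <- regmatches(alias, regexec("([A-Za-z0-9_.-]+)\\(display_short\\)",
                                 alias))[[1]]
  if (length(m) == 2L) return(m[2])
  sub("^[^:]*:", "", id)
}

#' Read an interactome into a graph
#'
#' Accepts PSI-MITAB 2.5 (tab-separated, interactor identifiers in
#' columns 1-2 and aliases in columns 5-6; gene symbols are taken from
#' `(gene name)` / `(display_short)` alias entries, or mapped through
#' `aliasMap`) or a plain 2-column TSV of symbol pairs with an optional
#' logical `directed` column. Redundant evidence lines are collapsed:
#' the graph keeps one edge per interacting pair.
#'
#' @param path input path.
#' @param format `"auto"` (default: MITAB when the header or column count
#'   says so), `"mitab"`, or `"tsv"`.
#' @param aliasMap optional named character vector mapping raw interactor
#'   identifiers to gene symbols.
#' @return an [igraph::graph] (undirected unless the TSV carried a
#'   `directed` column with any `TRUE`, in which case directed with
#'   undirected rows expanded to both directions).
#' @export
readInteractome <- function(path, format = c("auto", "mitab", "tsv"),
                            aliasMap = NULL) {
  format <- match.arg(format)
  first <- readLines(path, n = 1L)
  ncols <- length(strsplit(first, "\t", fixed = TRUE)[[1]])
  if (format == "auto")
    format <- if (ncols >= 15L || grepl("^#ID", first)) "mitab" else "tsv"
  if (format == "mitab") {
    df <- utils::read.delim(path, header = grepl("^#", first),
                            comment.char = "", stringsAsFactors = FALSE)
    a <- df[[1]]; b <- df[[2]]
    if (!is.null(aliasMap)) {
      idOf <- function(x) sub("^[^:]*:", "", x)
      sa <- unname(aliasMap[idOf(a)]); sb <- unname(aliasMap[idOf(b)])
      sa[is.na(sa)] <- idOf(a)[is.na(sa)]
      sb[is.na(sb)] <- idOf(b)[is.na(sb)]
    } else {
      sa <- mapply(.mitabSymbol, df[[5]], a, USE.NAMES = FALSE)
      sb <- mapply(.mitabSymbol, df[[6]], b, USE.NAMES = FALSE)
    }
    edges <- unique(data.frame(a = sa, b = sb, stringsAsFactors = FALSE))
    return(igraph::graph_from_data_frame(edges, directed = FALSE))
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("interactome TSV needs at least two columns")
  directedCol <- df$directed %||% rep(FALSE, nrow(df))
  directedCol <- as.logical(directedCol)
  if (any(directedCol)) {
    und <- df[!directedCol, 1:2]
    edges <- rbind(setNames(df[directedCol, 1:2], c("a", "b")),
                   setNames(und, c("a", "b")),
                   setNames(und[2:1], c("a", "b")))
    igraph::graph_from_data_frame(unique(edges), directed = TRUE)
  } else {
    igraph::graph_from_data_frame(unique(df[1:2]), directed = FALSE)
  }
}

#' Read a TF-to-target regulation table
#'
#' Tab-separated with at least columns `tf`, `target`, `mode` (mode in
#' `{activation, repression, unknown}`); duplicate (tf, target) pairs are
#' collapsed, keeping the first mode.
#'
#' @param path TSV path.
#' @return data.frame with columns tf, target, mode.
#' @export
readTFTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("tf", "target", "mode"), names(df))
  if (length(miss))
    stop("TF table ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  df$mode[!df$mode %in% c("activation", "repression")] <- "unknown"
  df[!duplicated(df[c("tf", "target")]), c("tf", "target", "mode")]
}

#' Read a signed-interaction table
#'
#' Tab-separated with columns `source`, `target`, `sign` (sign in
#' `{activation, inhibition}`). A later row for the same (source, target)
#' pair overwrites the earlier one.
#'
#' @param path TSV path.
#' @return data.frame with unique (source, target) rows.
#' @export
readSignTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("source", "target", "sign"), names(df))
  if (length(miss))
    stop("sign table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$sign), c("activation", "inhibition"))
  if (length(bad))
    stop("sign values must be activation/inhibition; found: ",
         paste(bad, collapse = ", "))
  df[!duplicated(df[c("source", "target")], fromLast = TRUE), ]
}
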