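#' @import methods
NULL

#' Boolean regulatory rule
#'
#' One update rule of a Boolean gene regulatory network. A rule stores its
#' target gene, a canonical text rendering in the `and/or/not` dialect, the
#' parsed expression tree, and (for rules built from signed regulator lists)
#' the activator/inhibitor decomposition that makes the rule nested
#' canalyzing.
#'
#' @slot target gene symbol the rule updates.
#' @slot text canonical rule expression text.
#' @slot ast parsed expression tree (nested lists of `op`/`args` nodes).
#' @slot regulators gene symbols appearing in the rule body.
#' @slot meta list describing the rule family: `type` is one of `"frozen"`
#'   (identity on the target, used for input genes without regulators),
#'   `"ncf"` (built from activator/inhibitor sets under a canalyzing
#'   scheme, with elements `activators`, `inhibitors`, `scheme`), or
#'   `"expr"` (free-form parsed expression).
#' @export
setClass("BooleanRule", representation(
  target = "character",
  text = "character",
  ast = "list",
  regulators = "character",
  meta = "list"
))

setValidity("BooleanRule", function(object) {
  msg <- character()
  if (length(object@target) != 1L || !nzchar(object@target))
    msg <- c(msg, "target must be a single non-empty gene symbol")
  if (length(object@text) != 1L)
    msg <- c(msg, "text must be a single string")
  if (!object@meta$type %in% c("frozen", "ncf", "expr"))
    msg <- c(msg, "meta$type must be 'frozen', 'ncf' or 'expr'")
  if (length(msg)) msg else TRUE
})

#' Boolean gene regulatory network
#'
#' A synchronous Boolean network: an ordered gene set, one update rule per
#' gene, and (optionally) the signed, directed edge list the rules were
#' assembled from. The gene order is fixed at construction and indexes every
#' network state vector, so that trajectories are reproducible across runs.
#'
#' @slot genes ordered character vector of unique gene symbols; positions
#'   define the 0/1 state-vector indexing.
#' @slot rules list of [BooleanRule-class] objects, one per gene, in gene
#'   order.
#' @slot edges data.frame with columns `source`, `target`, `sign`
#'   (`"activation"`/`"inhibition"`) and `provenance` (`"interactome"`,
#'   `"intermediary"`, `"tf_table"`, `"manual"` or `"rules"`); may have zero
#'   rows for networks parsed from a rule file.
#' @slot cache environment used internally to memoize the compiled update
#'   map; not part of the network's value.
#' @export
setClass("BooleanNetwork", representation(
  genes = "character",
  rules = "list",
  edges = "data.frame",
  cache = "environment"
))

setValidity("BooleanNetwork", function(object) {
  msg <- character()
  g <- object@genes
  if (anyDuplicated(g)) msg <- c(msg, "gene symbols must be unique")
  if (length(object@rules) != length(g))
    msg <- c(msg, "exactly one rule per gene is required")
  tg <- vapply(object@rules, function(r) r@target, character(1))
  if (!identical(tg, g))
    msg <- c(msg, "rules must be ordered by gene, one rule per gene")
  regs <- unique(unlist(lapply(object@rules, function(r) r@regulators)))
  bad <- setdiff(regs, g)
  if (length(bad))
    msg <- c(msg, paste0("rule references undeclared gene(s): ",
                         paste(bad, collapse = ", ")))
  if (nrow(object@edges)) {
    if (!all(c("source", "target", "sign") %in% names(object@edges)))
      msg <- c(msg, "edges need columns source, target, sign")
    else {
      bade <- setdiff(unique(c(object@edges$source, object@edges$target)), g)
      if (length(bade))
        msg <- c(msg, paste0("edge endpoints outside the network: ",
                             paste(bade, collapse = ", ")))
      if (anyDuplicated(object@edges[c("source", "target")]))
        msg <- c(msg, "duplicate (source, target) edges")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Attractor of a synchronous Boolean network
#'
#' The cyclic set of states a deterministic trajectory repeats forever.
#' States are stored in cycle order, rotated so the lexicographically
#' smallest state comes first; this canonical form makes attractors from
#' different cells comparable by equality.
#'
#' @slot states list of 0/1 integer state vectors in cycle order (canonical
#'   rotation).
#' @slot period cycle length; 1 for a fixed point.
#' @slot kind `"singleton"` (period 1) or `"cyclic"`.
#' @export
setClass("Attractor", representation(
  states = "list",
  period = "integer",
  kind = "character"
))

setValidity("Attractor", function(object) {
  msg <- character()
  if (object@period != length(object@states))
    msg <- c(msg, "period must equal the number of cycle states")
  keys <- vapply(object@states, packState, character(1))
  if (anyDuplicated(keys)) msg <- c(msg, "cycle states must be distinct")
  if (!object@kind %in% c("singleton", "cyclic"))
    msg <- c(msg, "kind must be 'singleton' or 'cyclic'")
  if ((object@period == 1L) != (object@kind == "singleton"))
    msg <- c(msg, "kind 'singleton' iff period 1")
  if (length(msg)) msg else TRUE
})

setClassUnion("AttractorOrNULL", c("Attractor", "NULL"))

#' Synchronous trajectory of a Boolean network
#'
#' The state sequence produced by iterating the synchronous update map from
#' an initial state until a state repeats (closing the attractor cycle) or a
#' step budget is exhausted. An exhausted search carries no attractor and is
#' reported as a "no result" cell rather than an error.
#'
#' @slot states list of visited states, starting at the initial state; the
#'   last recorded state equals the state at `firstRepeatIndex` when an
#'   attractor was found.
#' @slot firstRepeatIndex 1-based index into `states` where the repeated
#'   state first occurred; `NA` when the step budget ran out.
#' @slot stepsTaken number of synchronous updates performed.
#' @slot attractor the terminal [Attractor-class], or `NULL` for no result.
#' @export
setClass("Trajectory", representation(
  states = "list",
  firstRepeatIndex = "integer",
  stepsTaken = "integer",
  attractor = "AttractorOrNULL"
))

#' Per-gene binarization result
#'
#' Result of thresholding one gene's expression vector with the
#' step-function algorithm: the family of optimal step functions of the
#' sorted vector is computed by dynamic programming, the strongest
#' discontinuity of each family member is located, and the threshold is
#' placed at the midpoint of the gap selected by the (lower) median
#' strongest-discontinuity location.
#'
#' @slot threshold separation threshold `t`; a value is called expressed
#'   (bit 1) iff it is `>= t`.
#' @slot bits 0/1 integer vector in the original cell order.
#' @slot locations strongest-discontinuity rank location for each member of
#'   the step-function family (most discontinuities first).
#' @slot scores discontinuity scores paired with `locations`.
#' @slot quality dispersion of the strongest-discontinuity locations
#'   (median absolute deviation of `locations`, normalized by `N`); small
#'   values mean the family agrees on one gap.
#' @slot degenerate `TRUE` when the input vector was constant and no
#'   threshold exists.
#' @export
setClass("BinarizationResult", representation(
  threshold = "numeric",
  bits = "integer",
  locations = "integer",
  scores = "numeric",
  quality = "numeric",
  degenerate = "logical"
))
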