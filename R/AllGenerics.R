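#' Genes of a Boolean network
#'
#' @param x a [BooleanNetwork-class].
#' @return character vector of gene symbols in network (state-vector) order.
#' @export
setGeneric("networkGenes", function(x) standardGeneric("networkGenes"))

#' Number of genes in a Boolean network
#' @param x a [BooleanNetwork-class].
#' @export
setGeneric("networkSize", function(x) standardGeneric("networkSize"))

#' Update rules of a Boolean network
#' @param x a [BooleanNetwork-class].
#' @return named list of [BooleanRule-class] objects, one per gene.
#' @export
setGeneric("networkRules", function(x) standardGeneric("networkRules"))

#' Signed edge list of a Boolean network
#' @param x a [BooleanNetwork-class].
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Rule text of a network or rule
#' @param x a [BooleanNetwork-class] or [BooleanRule-class].
#' @export
setGeneric("ruleText", function(x) standardGeneric("ruleText"))

#' Cycle states of an attractor
#' @param x an [Attractor-class].
#' @export
setGeneric("attractorStates", function(x) standardGeneric("attractorStates"))

#' Cycle length of an attractor
#' @param x an [Attractor-class].
#' @export
setGeneric("attractorPeriod", function(x) standardGeneric("attractorPeriod"))

#' Kind of an attractor (singleton or cyclic)
#' @param x an [Attractor-class].
#' @export
setGeneric("attractorKind", function(x) standardGeneric("attractorKind"))

#' Terminal attractor of a trajectory
#' @param x a [Trajectory-class].
#' @return an [Attractor-class], or `NULL` when the search exhausted its
#'   step budget (a "no result" cell).
#' @export
setGeneric("trajectoryAttractor",
           function(x) standardGeneric("trajectoryAttractor"))

#' Did a trajectory fail to reach a cycle within the step budget?
#' @param x a [Trajectory-class].
#' @export
setGeneric("noResult", function(x) standardGeneric("noResult"))

#' Separation threshold of a binarization result
#' @param x a [BinarizationResult-class].
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' Binarized bits in original cell order
#' @param x a [BinarizationResult-class].
#' @export
setGeneric("binaryBits", function(x) standardGeneric("binaryBits"))
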