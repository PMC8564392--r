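#' @describeIn BooleanNetwork gene symbols in state-vector order.
#' @param x object.
#' @export
setMethod("networkGenes", "BooleanNetwork", function(x) x@genes)

#' @describeIn BooleanNetwork number of genes.
#' @export
setMethod("networkSize", "BooleanNetwork", function(x) length(x@genes))

#' @describeIn BooleanNetwork named list of update rules.
#' @export
setMethod("networkRules", "BooleanNetwork",
          function(x) setNames(x@rules, x@genes))

#' @describeIn BooleanNetwork signed directed edge list.
#' @export
setMethod("networkEdges", "BooleanNetwork", function(x) x@edges)

#' @describeIn BooleanNetwork canonical rule text, one element per gene.
#' @export
setMethod("ruleText", "BooleanNetwork",
          function(x) setNames(vapply(x@rules, function(r) r@text,
                                      character(1)), x@genes))

#' @describeIn BooleanRule canonical rule expression text.
#' @export
setMethod("ruleText", "BooleanRule", function(x) x@text)

#' @describeIn Attractor cycle states (canonical rotation).
#' @param x object.
#' @export
setMethod("attractorStates", "Attractor", function(x) x@states)

#' @describeIn Attractor cycle length.
#' @export
setMethod("attractorPeriod", "Attractor", function(x) x@period)

#' @describeIn Attractor `"singleton"` or `"cyclic"`.
#' @export
setMethod("attractorKind", "Attractor", function(x) x@kind)

#' @describeIn Trajectory terminal attractor (`NULL` for no result).
#' @param x object.
#' @export
setMethod("trajectoryAttractor", "Trajectory", function(x) x@attractor)

#' @describeIn Trajectory `TRUE` when no cycle was reached in budget.
#' @export
setMethod("noResult", "Trajectory", function(x) is.null(x@attractor))

#' @describeIn BinarizationResult separation threshold `t`.
#' @param x object.
#' @export
setMethod("threshold", "BinarizationResult", function(x) x@threshold)

#' @describeIn BinarizationResult 0/1 bits in original cell order.
#' @export
setMethod("binaryBits", "BinarizationResult", function(x) x@bits)

setMethod("show", "BooleanNetwork", function(object) {
  cat(sprintf("BooleanNetwork with %d genes, %d signed edges\n",
              length(object@genes), nrow(object@edges)))
  n <- min(5L, length(object@genes))
  for (i in seq_len(n))
    cat(sprintf("  %s* = %s\n", object@genes[i], object@rules[[i]]@text))
  if (length(object@genes) > n)
    cat(sprintf("  ... and %d more rules\n", length(object@genes) - n))
})

setMethod("show", "Attractor", function(object) {
  cat(sprintf("%s Attractor, period %d\n", object@kind, object@period))
  for (s in object@states) cat(" ", packState(s), "\n")
})

setMethod("show", "Trajectory", function(object) {
  if (is.null(object@attractor)) {
    cat(sprintf("Trajectory: no result after %d steps\n", object@stepsTaken))
  } else {
    cat(sprintf(
      "Trajectory: %d steps, cycle entered at step %d (period %d)\n",
      object@stepsTaken, object@firstRepeatIndex - 1L,
      object@attractor@period))
  }
})

setMethod("show", "BinarizationResult", function(object) {
  if (object@degenerate) {
    cat("BinarizationResult: degenerate (constant vector)\n")
  } else {
    cat(sprintf(
      "BinarizationResult: t = %.4g, %d/%d cells called expressed, quality %.3g\n",
      object@threshold, sum(object@bits), length(object@bits),
      object@quality))
  }
})

#' Structural equality of Boolean networks
#'
#' Two networks are equal when they have the same genes in the same order
#' and the same canonical rule text for every gene. Edge provenance is
#' metadata and is not compared.
#'
#' @param e1,e2 [BooleanNetwork-class] objects.
#' @return logical scalar.
#' @export
setMethod("==", signature("BooleanNetwork", "BooleanNetwork"),
          function(e1, e2) {
            identical(e1@genes, e2@genes) &&
              identical(unname(ruleText(e1)), unname(ruleText(e2)))
          })

#' @rdname eq-BooleanNetwork-BooleanNetwork-method
#' @export
setMethod("!=", signature("BooleanNetwork", "BooleanNetwork"),
          function(e1, e2) !(e1 == e2))
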