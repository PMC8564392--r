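# Step-function (BASC-style) binarization of per-gene expression vectors.
# The sorted vector is approximated by the family of optimal monotone step
# functions with decreasing discontinuity counts; the threshold sits in the
# gap picked by the median strongest-discontinuity location.

.bascEps <- 1e-12   # guards the discontinuity score against /0 on exact fits

isDegenerateVector <- function(v) {
  length(unique(v)) < 2L
}

#' Optimal step-function family of a sorted expression vector
#'
#' For each discontinuity count \eqn{j \in \{1, \dots, N-2\}} computes the
#' monotone step function with exactly `j` discontinuities minimizing the
#' total squared deviation from the sorted input, with levels equal to the
#' means of their intervals. Computed by dynamic programming over
#' breakpoint placements; cost ties are broken by the lexicographically
#' smallest breakpoint tuple. The family is returned with the most
#' discontinuities first.
#'
#' @param v numeric vector sorted in ascending order, length at least 3,
#'   not constant.
#' @return list of step functions, each a list with elements `breakpoints`
#'   (positions `d`; a breakpoint `d` separates ranks `d` and `d+1`),
#'   `levels` (interval means), `nSteps`, and `sse` (total squared error).
#' @examples
#' fam <- optimalStepFunctions(c(1, 2, 10))
#' fam[[1]]$breakpoints  # 2: the optimal single split is after rank 2
#' @export
optimalStepFunctions <- function(v) {
  if (is.unsorted(v)) stop("input vector must be sorted ascending")
  N <- length(v)
  if (N < 3L) stop("need at least 3 values to estimate a threshold")
  if (isDegenerateVector(v))
    stop("degenerate: no discontinuity (constant vector)")
  dp <- bascDP(as.numeric(v))
  lapply(seq_along(dp$breakpoints), function(k) {
    bp <- dp$breakpoints[[k]]
    bounds <- c(0L, bp, N)
    levels <- vapply(seq_len(length(bounds) - 1L), function(s) {
      mean(v[(bounds[s] + 1L):bounds[s + 1L]])
    }, numeric(1))
    structure(list(breakpoints = bp, levels = levels,
                   nSteps = length(bp) + 1L, sse = dp$sse[[k]]),
              class = "StepFunction")
  })
}

#' Strongest discontinuity of a step function
#'
#' Scores each breakpoint as its level jump divided by the step function's
#' approximation error (plus a small constant guarding exact fits), and
#' returns the location and score of the best one; ties go to the smallest
#' location. Jump heights and squared errors are both invariant under
#' adding a constant to the data, so the score is shift invariant.
#'
#' @param f a step function as returned by [optimalStepFunctions()].
#' @param v the sorted vector `f` approximates (unused beyond validation;
#'   the jump heights and error are carried by `f`).
#' @return list with `location` (rank index: the discontinuity lies between
#'   ranks `location` and `location + 1`) and `score`.
#' @export
strongestDiscontinuity <- function(f, v = NULL) {
  if (length(f$breakpoints) < 1L) stop("step function has no breakpoint")
  jumps <- diff(f$levels)
  scores <- jumps / (f$sse + .bascEps)
  i <- which.max(scores)  # which.max takes the first (smallest) on ties
  list(location = f$breakpoints[i], score = scores[i])
}

#' Binarization threshold of one expression vector
#'
#' Runs the full step-function procedure on one gene: sort the values,
#' compute the optimal step-function family, locate each member's strongest
#' discontinuity, take the (lower) median location across the family, and
#' place the threshold `t` at the midpoint of the corresponding gap between
#' consecutive sorted values. A cell is called expressed (bit 1) iff its
#' value is `>= t`; because `t` lies strictly inside a gap, no observed
#' value equals `t`. The quality score is the median absolute deviation of
#' the strongest-discontinuity locations divided by `N`: near 0 when the
#' whole family points at the same gap.
#'
#' @param v numeric expression vector in original cell order (at least 3
#'   values, not constant).
#' @return a [BinarizationResult-class].
#' @examples
#' r <- computeThreshold(c(1, 1, 1, 10, 10, 10))
#' threshold(r)   # 5.5
#' binaryBits(r)  # 0 0 0 1 1 1
#' @export
computeThreshold <- function(v) {
  N <- length(v)
  if (N < 3L) stop("need at least 3 cells to estimate a threshold")
  if (isDegenerateVector(v))
    stop("degenerate: no discontinuity (constant vector)")
  ord <- order(v)
  u <- v[ord]
  fam <- optimalStepFunctions(u)
  strongest <- lapply(fam, strongestDiscontinuity)
  locs <- vapply(strongest, `[[`, numeric(1), "location")
  scores <- vapply(strongest, `[[`, numeric(1), "score")
  sorted <- sort(locs)
  loc <- sorted[floor((length(sorted) + 1) / 2)]  # lower median
  t <- (u[loc] + u[loc + 1L]) / 2
  new("BinarizationResult",
      threshold = t,
      bits = as.integer(v >= t),
      locations = as.integer(locs),
      scores = scores,
      quality = stats::mad(locs, constant = 1) / N,
      degenerate = FALSE)
}

.degenerateResult <- function(v, fill) {
  new("BinarizationResult",
      threshold = NA_real_,
      bits = rep(as.integer(fill), length(v)),
      locations = integer(), scores = numeric(),
      quality = NA_real_, degenerate = TRUE)
}

#' Binarize a genes-by-cells expression matrix
#'
#' Applies [computeThreshold()] to each gene row independently. Degenerate
#' (constant) rows carry no threshold; by default they are mapped to all-0
#' ("not expressed") with a warning, or dropped under
#' `degenerate = "drop"`.
#'
#' @param expr numeric matrix, genes in rows, cells in columns; at least 3
#'   cells.
#' @param degenerate how to handle constant rows: `"all_zero"` (default),
#'   `"all_one"`, or `"drop"`.
#' @return list with `bits` (0/1 integer matrix, same dimnames as the
#'   retained rows of `expr`), `results` (per-gene
#'   [BinarizationResult-class] objects), and `thresholds` (data.frame
#'   with columns gene, threshold, quality, degenerate).
#' @export
binarizeMatrix <- function(expr, degenerate = c("all_zero", "all_one", "drop")) {
  degenerate <- match.arg(degenerate)
  expr <- as.matrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 cells to binarize")
  if (any(expr < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(expr)))
    rownames(expr) <- paste0("g", seq_len(nrow(expr)))
  fill <- if (degenerate == "all_one") 1L else 0L
  results <- vector("list", nrow(expr))
  names(results) <- rownames(expr)
  degen <- logical(nrow(expr))
  for (i in seq_len(nrow(expr))) {
    row <- expr[i, ]
    if (isDegenerateVector(row)) {
      degen[i] <- TRUE
      results[[i]] <- .degenerateResult(row, fill)
    } else {
      results[[i]] <- computeThreshold(row)
    }
  }
  if (any(degen))
    warning(sum(degen), " constant gene row(s) ",
            if (degenerate == "drop") "dropped"
            else paste0("mapped to all-", fill),
            ": ", paste(head(rownames(expr)[degen], 5L), collapse = ", "),
            if (sum(degen) > 5L) ", ..." else "")
  keep <- if (degenerate == "drop") which(!degen) else seq_len(nrow(expr))
  bits <- t(vapply(results[keep], binaryBits, integer(ncol(expr))))
  dimnames(bits) <- list(rownames(expr)[keep], colnames(expr))
  list(bits = bits,
       results = results[keep],
       thresholds = data.frame(
         gene = rownames(expr)[keep],
         threshold = vapply(results[keep], threshold, numeric(1)),
         quality = vapply(results[keep], function(r) r@quality, numeric(1)),
         degenerate = degen[keep],
         stringsAsFactors = FALSE))
}

#' Write binarization outputs
#'
#' Writes the 0/1 matrix as a TSV (cells as columns) and the per-gene
#' thresholds as a CSV.
#'
#' @param bin result of [binarizeMatrix()].
#' @param bitsFile,thresholdsFile output paths.
#' @return `bin`, invisibly.
#' @export
writeBinarization <- function(bin, bitsFile, thresholdsFile) {
  utils::write.table(bin$bits, bitsFile, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.csv(bin$thresholds, thresholdsFile, row.names = FALSE)
  invisible(bin)
}
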