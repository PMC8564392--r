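#' @importFrom stats rnorm rpois runif rlnorm quantile median mad setNames
#' @importFrom utils head tail read.delim write.csv combn
#' @importFrom Rcpp sourceCpp
#' @useDynLib attractome, .registration = TRUE
NULL

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Pack a 0/1 state vector into a hashable string key.
packState <- function(bits) paste(bits, collapse = "")

unpackState <- function(key) as.integer(strsplit(key, "", fixed = TRUE)[[1]])

# stderr logging used by the pipeline and construction stages
logMsg <- function(...) message(sprintf(...))

`%||%` <- function(a, b) if (is.null(a)) b else a
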