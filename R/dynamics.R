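# Synchronous Boolean dynamics: all genes recompute their next value
# simultaneously from the current state. Networks whose rules all come
# from the canalyzing constructor (or are frozen inputs) are updated
# through sparse activator/inhibitor matrices; free-form parsed rules
# fall back to compiled expression evaluation per gene.

compileNetwork <- function(net) {
  if (!is.null(net@cache$step)) return(net@cache$step)
  n <- length(net@genes)
  index <- setNames(seq_len(n), net@genes)
  types <- vapply(net@rules, function(r) r@meta$type, character(1))
  if (all(types %in% c("frozen", "ncf"))) {
    src <- integer(); dst <- integer(); sgn <- integer()
    scheme <- character(n)
    for (i in seq_len(n)) {
      r <- net@rules[[i]]
      if (r@meta$type == "frozen") next
      scheme[i] <- r@meta$scheme
      for (a in r@meta$activators) {
        src <- c(src, index[[a]]); dst <- c(dst, i); sgn <- c(sgn, 1L)
      }
      for (b in r@meta$inhibitors) {
        src <- c(src, index[[b]]); dst <- c(dst, i); sgn <- c(sgn, -1L)
      }
    }
    actM <- Matrix::sparseMatrix(i = dst[sgn > 0], j = src[sgn > 0],
                                 x = 1, dims = c(n, n))
    inhM <- Matrix::sparseMatrix(i = dst[sgn < 0], j = src[sgn < 0],
                                 x = 1, dims = c(n, n))
    hasAct <- Matrix::rowSums(actM) > 0
    hasInh <- Matrix::rowSums(inhM) > 0
    frozen <- types == "frozen"
    inhDom <- scheme == "inhibitor_dominant"
    step <- function(s) {
      anyAct <- as.vector(actM %*% s) > 0
      anyInh <- as.vector(inhM %*% s) > 0
      vID <- (!hasAct | anyAct) & (!hasInh | !anyInh)
      vAD <- (hasAct & anyAct) | (hasInh & !anyInh)
      out <- as.integer(ifelse(inhDom, vID, vAD))
      out[frozen] <- s[frozen]
      out
    }
  } else {
    exprs <- lapply(net@rules, function(r) compileAST(r@ast, index))
    evalEnv <- new.env(parent = baseenv())
    step <- function(s) {
      assign(".s", s == 1L, envir = evalEnv)
      vapply(exprs, function(e) as.integer(eval(e, evalEnv)), integer(1))
    }
  }
  net@cache$step <- step
  step
}

checkState <- function(net, state) {
  if (length(state) != length(net@genes))
    stop("state length ", length(state), " does not match network size ",
         length(net@genes))
  s <- as.integer(state)
  if (any(is.na(s)) || any(s < 0L | s > 1L))
    stop("state entries must be 0 or 1")
  s
}

#' One synchronous update of a Boolean network
#'
#' Computes the next network state: every gene evaluates its rule against
#' the *current* state only, so all genes switch simultaneously (a network
#' `A* = B; B* = A` swaps the two bits rather than propagating one of them
#' sequentially).
#'
#' @param net a [BooleanNetwork-class].
#' @param state 0/1 integer vector, one entry per gene in network order.
#' @return the next state, same shape.
#' @examples
#' net <- parseRules(c("A* = B", "B* = A"))
#' synchronousStep(net, c(0L, 1L))  # 1 0
#' @export
synchronousStep <- function(net, state) {
  s <- checkState(net, state)
  compileNetwork(net)(s)
}

canonicalAttractor <- function(cycleStates) {
  keys <- vapply(cycleStates, packState, character(1))
  i0 <- which.min(keys)
  if (i0 > 1L)
    cycleStates <- c(cycleStates[i0:length(cycleStates)],
                     cycleStates[seq_len(i0 - 1L)])
  p <- length(cycleStates)
  new("Attractor", states = cycleStates, period = as.integer(p),
      kind = if (p == 1L) "singleton" else "cyclic")
}

#' Canonical string key of an attractor
#'
#' Concatenates the packed bit strings of the cycle states in canonical
#' rotation; two attractors are the same cycle iff their keys are equal,
#' which makes per-cell attractors comparable across a group.
#'
#' @param attr an [Attractor-class].
#' @return a single string.
#' @export
attractorKey <- function(attr) {
  paste(vapply(attr@states, packState, character(1)), collapse = "|")
}

#' Simulate a trajectory to its attractor
#'
#' Iterates the synchronous update map from an initial state, hashing each
#' visited state with its first-seen step index. On the first revisit the
#' cycle is closed: the attractor is the state sequence from the first
#' occurrence of the revisited state up to the step before the revisit,
#' stored in canonical rotation. If `maxSteps` updates pass without a
#' revisit the search reports "no result" — a value, not an error — so
#' that no-result rates are reproducible for a given, logged step budget.
#'
#' @param net a [BooleanNetwork-class].
#' @param initial 0/1 initial state in network gene order (e.g., one
#'   cell's binarized expression).
#' @param maxSteps step budget (default 10000).
#' @param cache optional environment memoizing the transition map across
#'   calls on the same network (state key to next state); useful when many
#'   cells of one sample are simulated on one network.
#' @return a [Trajectory-class]; its attractor is `NULL` on no result.
#' @examples
#' net <- parseRules("A* = not A")
#' tr <- simulateToAttractor(net, 0L)
#' attractorPeriod(trajectoryAttractor(tr))  # 2
#' @export
simulateToAttractor <- function(net, initial, maxSteps = 10000L,
                                cache = NULL) {
  stopifnot(maxSteps >= 1L)
  s <- checkState(net, initial)
  step <- compileNetwork(net)
  visited <- new.env(parent = emptyenv(), size = 256L)
  states <- vector("list", 64L)
  k <- 1L
  states[[1L]] <- s
  assign(packState(s), 1L, envir = visited)
  repeat {
    if (is.null(cache)) {
      nxt <- step(s)
    } else {
      key <- packState(s)
      nxt <- get0(key, envir = cache, inherits = FALSE)
      if (is.null(nxt)) {
        nxt <- step(s)
        assign(key, nxt, envir = cache)
      }
    }
    k <- k + 1L
    if (k > length(states)) states <- c(states, vector("list", length(states)))
    states[[k]] <- nxt
    nk <- packState(nxt)
    seen <- get0(nk, envir = visited, inherits = FALSE)
    if (!is.null(seen)) {
      traj <- states[seq_len(k)]
      cyc <- traj[seq.int(seen, k - 1L)]
      return(new("Trajectory", states = traj,
                 firstRepeatIndex = as.integer(seen),
                 stepsTaken = k - 1L,
                 attractor = canonicalAttractor(cyc)))
    }
    if (k - 1L >= maxSteps) {
      return(new("Trajectory", states = states[seq_len(k)],
                 firstRepeatIndex = NA_integer_,
                 stepsTaken = k - 1L,
                 attractor = NULL))
    }
    assign(nk, k, envir = visited)
    s <- nxt
  }
}

#' Exhaustive attractor enumeration over the full state space
#'
#' Builds the complete synchronous transition map over all \eqn{2^n}
#' states and extracts every cycle together with its basin size (the
#' number of states whose trajectory ends in it). Basin sizes always sum
#' to \eqn{2^n}: basins partition the state space. Intended as the exact
#' reference for trajectory-based search on small networks; refuses
#' networks above 22 genes, where trajectory mode is the only option.
#'
#' @param net a [BooleanNetwork-class] with at most 22 genes.
#' @return list with `attractors` (list of [Attractor-class] in canonical
#'   form) and `basinSizes` (integer vector aligned with `attractors`).
#' @examples
#' net <- parseRules(c("A* = B", "B* = A"))
#' enumerateAttractors(net)$basinSizes  # 1 1 2
#' @export
enumerateAttractors <- function(net) {
  n <- length(net@genes)
  if (n > 22L)
    stop("state space 2^", n, " too large to enumerate; ",
         "use simulateToAttractor from chosen initial states instead")
  step <- compileNetwork(net)
  total <- as.integer(2^n)
  weights <- 2^(seq_len(n) - 1L)
  idxBits <- function(idx) as.integer((idx %/% weights) %% 2L)
  nxt <- integer(total)
  for (i in seq_len(total)) {
    nxt[i] <- sum(step(idxBits(i - 1L)) * weights) + 1L
  }
  attractorOf <- integer(total)   # 0 = unassigned
  onPath <- integer(total)        # position on the current path, 0 if not
  attractors <- list()
  for (start in seq_len(total)) {
    if (attractorOf[start] != 0L) next
    path <- integer(0)
    v <- start
    while (attractorOf[v] == 0L && onPath[v] == 0L) {
      path <- c(path, v)
      onPath[v] <- length(path)
      v <- nxt[v]
    }
    if (onPath[v] != 0L) {  # new cycle discovered on this path
      cyc <- path[onPath[v]:length(path)]
      id <- length(attractors) + 1L
      attractors[[id]] <- canonicalAttractor(lapply(cyc - 1L, idxBits))
      attractorOf[path] <- id
    } else {
      attractorOf[path] <- attractorOf[v]
    }
    onPath[path] <- 0L
  }
  list(attractors = attractors,
       basinSizes = as.integer(tabulate(attractorOf, length(attractors))))
}
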