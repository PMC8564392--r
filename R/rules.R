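# Boolean rule dialect: one rule per line, "GENE* = expr", operators
# and/or/not (aliases & | ! and the unicode connectives), parentheses,
# "#" comments. Genes with no rule line are frozen inputs (x* = x).

astVar <- function(name) list(op = "var", name = name)
astNot <- function(x) list(op = "not", args = list(x))

# n-ary AND/OR nodes; single-argument nodes collapse to the argument and
# nested same-operator children are flattened, which makes the rendered
# text canonical.
astJoin <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (identical(a$op, op)) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  if (length(flat) == 1L) flat[[1]] else list(op = op, args = flat)
}

astSymbols <- function(ast) {
  if (ast$op == "var") return(ast$name)
  unique(unlist(lapply(ast$args, astSymbols)))
}

evalAST <- function(ast, value) {
  switch(ast$op,
    var = value[[ast$name]],
    not = !evalAST(ast$args[[1]], value),
    and = all(vapply(ast$args, evalAST, logical(1), value = value)),
    or  = any(vapply(ast$args, evalAST, logical(1), value = value)),
    stop("unknown AST node: ", ast$op)
  )
}

renderAST <- function(ast) {
  switch(ast$op,
    var = ast$name,
    not = {
      inner <- ast$args[[1]]
      body <- renderAST(inner)
      if (inner$op %in% c("and", "or")) body <- paste0("(", body, ")")
      paste0("not ", body)
    },
    and = paste(vapply(ast$args, function(a) {
      b <- renderAST(a)
      if (a$op == "or") paste0("(", b, ")") else b
    }, character(1)), collapse = " and "),
    or = paste(vapply(ast$args, function(a) {
      b <- renderAST(a)
      if (a$op == "and") paste0("(", b, ")") else b
    }, character(1)), collapse = " or ")
  )
}

# Compile an AST to an R expression over `.s`, a logical state vector,
# given the gene -> index map. Used by the synchronous update engine.
compileAST <- function(ast, index) {
  switch(ast$op,
    var = {
      i <- index[[ast$name]]
      if (is.null(i) || is.na(i)) stop("unknown gene in rule: ", ast$name)
      bquote(.s[.(i)])
    },
    not = bquote(!.(compileAST(ast$args[[1]], index))),
    and = Reduce(function(a, b) bquote(.(a) & .(b)),
                 lapply(ast$args, compileAST, index = index)),
    or = Reduce(function(a, b) bquote(.(a) | .(b)),
                lapply(ast$args, compileAST, index = index))
  )
}

tokenizeRule <- function(text, line = NA) {
  pat <- "\\(|\\)|&&|\\|\\||[&|!]|∧|∨|¬|[A-Za-z0-9_.:-]+"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  toks <- if (m[1] == -1) character() else regmatches(text, list(m))[[1]]
  leftover <- gsub(pat, "", text, perl = TRUE)
  leftover <- gsub("\\s", "", leftover)
  if (nzchar(leftover))
    stop(sprintf("rule parse error%s: unexpected character(s) '%s'",
                 if (is.na(line)) "" else paste0(" at line ", line), leftover))
  vapply(toks, function(tk) {
    switch(tk,
      "and" = , "AND" = , "&" = , "&&" = , "∧" = "AND",
      "or" = , "OR" = , "|" = , "||" = , "∨" = "OR",
      "not" = , "NOT" = , "!" = , "¬" = "NOT",
      "(" = "(", ")" = ")",
      tk)
  }, character(1), USE.NAMES = FALSE) -> kinds
  list(kinds = kinds, raw = toks)
}

parseExprText <- function(text, line = NA) {
  tk <- tokenizeRule(text, line)
  kinds <- tk$kinds
  raw <- tk$raw
  pos <- 1L
  peek <- function() if (pos <= length(kinds)) kinds[pos] else ""
  advance <- function() {
    v <- raw[pos]
    pos <<- pos + 1L
    v
  }
  fail <- function(what) {
    stop(sprintf("rule parse error%s: %s",
                 if (is.na(line)) "" else paste0(" at line ", line), what))
  }
  parsePrimary <- function() {
    k <- peek()
    if (k == "(") {
      advance()
      e <- parseOr()
      if (peek() != ")") fail("missing closing parenthesis")
      advance()
      e
    } else if (k == "NOT") {
      advance()
      astNot(parsePrimary())
    } else if (!k %in% c("", ")", "AND", "OR")) {
      astVar(advance())
    } else {
      fail(if (k == "") "unexpected end of expression"
           else paste0("unexpected token '", raw[pos], "'"))
    }
  }
  parseAnd <- function() {
    args <- list(parsePrimary())
    while (peek() == "AND") {
      advance()
      args <- c(args, list(parsePrimary()))
    }
    astJoin("and", args)
  }
  parseOr <- function() {
    args <- list(parseAnd())
    while (peek() == "OR") {
      advance()
      args <- c(args, list(parseAnd()))
    }
    astJoin("or", args)
  }
  e <- parseOr()
  if (peek() != "") fail(paste0("trailing token '", raw[pos], "'"))
  e
}

newRule <- function(target, ast, meta = list(type = "expr")) {
  new("BooleanRule",
      target = target,
      text = renderAST(ast),
      ast = ast,
      regulators = astSymbols(ast),
      meta = meta)
}

frozenRule <- function(gene) {
  newRule(gene, astVar(gene), meta = list(type = "frozen"))
}

newBooleanNetwork <- function(genes, rules, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(source = character(), target = character(),
                        sign = character(), provenance = character(),
                        stringsAsFactors = FALSE)
  new("BooleanNetwork", genes = genes, rules = unname(rules),
      edges = edges, cache = new.env(parent = emptyenv()))
}

#' Build a nested canalyzing rule from signed regulator sets
#'
#' Constructs the update rule of a target gene from its ordered activator
#' and inhibitor lists under one of two canalyzing schemes. Under
#' `inhibitor_dominant` (the default used throughout network assembly) the
#' rule is \eqn{(\neg i_1 \wedge \dots \wedge \neg i_m) \wedge (a_1 \vee
#' \dots \vee a_k)}: any active inhibitor forces the target off, otherwise
#' any active activator turns it on. Under `activator_dominant` the rule is
#' \eqn{(a_1 \vee \dots \vee a_k) \vee \neg(i_1 \vee \dots \vee i_m)}. With
#' no inhibitors both schemes reduce to the OR of the activators; with no
#' activators, to the AND of the negated inhibitors. Either way the result
#' is nested canalyzing in the listed variable order.
#'
#' @param target gene symbol the rule updates.
#' @param activators,inhibitors character vectors of regulator symbols;
#'   together nonempty, and disjoint.
#' @param scheme `"inhibitor_dominant"` or `"activator_dominant"`.
#' @return a [BooleanRule-class].
#' @examples
#' r <- buildNCF("G", activators = "A", inhibitors = "B")
#' ruleText(r)  # "not B and A"
#' @export
buildNCF <- function(target, activators = character(),
                     inhibitors = character(),
                     scheme = c("inhibitor_dominant", "activator_dominant")) {
  scheme <- match.arg(scheme)
  activators <- as.character(activators)
  inhibitors <- as.character(inhibitors)
  if (length(activators) == 0L && length(inhibitors) == 0L)
    stop("gene '", target, "' has no regulators; declare it a frozen input ",
         "(rule ", target, "* = ", target, ") instead of building a rule")
  both <- intersect(activators, inhibitors)
  if (length(both))
    stop("regulator(s) listed as both activator and inhibitor for '",
         target, "': ", paste(both, collapse = ", "))
  actOr <- if (length(activators))
    astJoin("or", lapply(activators, astVar)) else NULL
  if (scheme == "inhibitor_dominant") {
    parts <- lapply(inhibitors, function(i) astNot(astVar(i)))
    if (!is.null(actOr)) parts <- c(parts, list(actOr))
    ast <- astJoin("and", parts)
  } else {
    parts <- lapply(activators, astVar)
    if (length(inhibitors))
      parts <- c(parts, list(astNot(astJoin("or", lapply(inhibitors, astVar)))))
    ast <- astJoin("or", parts)
  }
  newRule(target, ast,
          meta = list(type = "ncf", activators = activators,
                      inhibitors = inhibitors, scheme = scheme))
}

#' Evaluate a Boolean rule on a network state
#'
#' Pure evaluation of one rule against the current state; the value of the
#' target at the next time point under synchronous updating.
#'
#' @param rule a [BooleanRule-class].
#' @param state 0/1 integer (or logical) state vector, named by gene, or
#'   unnamed with `genes` supplying the order.
#' @param genes gene symbols giving the positions of `state`; defaults to
#'   `names(state)`.
#' @return integer 0 or 1.
#' @examples
#' r <- parseRules("A* = not A")@rules[[1]]
#' evaluateRule(r, c(A = 0L))
#' @export
evaluateRule <- function(rule, state, genes = names(state)) {
  stopifnot(is(rule, "BooleanRule"))
  if (is.null(genes))
    stop("state must be named by gene or 'genes' must be given")
  v <- as.logical(as.integer(state))
  names(v) <- genes
  miss <- setdiff(rule@regulators, genes)
  if (length(miss))
    stop("state lacks regulator(s): ", paste(miss, collapse = ", "))
  as.integer(evalAST(rule@ast, as.list(v)))
}

#' Parse a Boolean network from rule text
#'
#' Reads the one-rule-per-line dialect (`GENE* = expr`, operators
#' `and/or/not` with `& | !` and the unicode connectives accepted as
#' aliases, `#` comments). Every symbol used on a right-hand side must
#' either have its own rule line or be listed in `frozen`; frozen symbols
#' receive the identity rule (their value is held across updates). The
#' network's gene order is the rule-line order, followed by frozen inputs
#' in order of first appearance, and indexes all state vectors.
#'
#' @param text rule text (single string or character vector of lines).
#' @param frozen gene symbols to treat as frozen inputs when they have no
#'   rule line of their own.
#' @return a [BooleanNetwork-class].
#' @examples
#' net <- parseRules("E* = (A and B) or (C and D)",
#'                   frozen = c("A", "B", "C", "D"))
#' networkGenes(net)
#' @export
parseRules <- function(text, frozen = character()) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("empty rule input: no rule lines found")
  targets <- character()
  asts <- list()
  ruleLine <- integer()
  for (i in keep) {
    ln <- trimws(lines[i])
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.:-]+)\\*?\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("rule parse error at line ", i,
           ": expected 'GENE* = expression', got '", ln, "'")
    g <- m[2]
    if (g %in% targets)
      stop("duplicate rule for gene '", g, "' at line ", i)
    targets <- c(targets, g)
    asts[[g]] <- parseExprText(m[3], line = i)
    ruleLine[g] <- i
  }
  # frozen inputs appended in first right-hand-side appearance order
  extra <- character()
  for (g in targets) {
    for (s in astSymbols(asts[[g]])) {
      if (!s %in% targets && !s %in% extra) {
        if (!s %in% frozen)
          stop("undeclared symbol '", s, "' on the right-hand side at line ",
               ruleLine[g], "; add a rule line or list it in 'frozen'")
        extra <- c(extra, s)
      }
    }
  }
  genes <- c(targets, extra)
  rules <- c(lapply(targets, function(g) newRule(g, asts[[g]])),
             lapply(extra, frozenRule))
  newBooleanNetwork(genes, rules)
}

#' Serialize a Boolean network to rule text
#'
#' Writes the canonical rule dialect, one `GENE* = expr` line per gene in
#' network order; frozen inputs appear as identity rules. Parsing the
#' output reproduces the network (structural equality), and writing a
#' just-parsed network reproduces the canonical text.
#'
#' @param net a [BooleanNetwork-class].
#' @param file optional path; when given, the text is written there.
#' @return the rule text as a single string (invisibly when `file` is set).
#' @export
writeRules <- function(net, file = NULL) {
  stopifnot(is(net, "BooleanNetwork"))
  txt <- paste(vapply(seq_along(net@genes), function(i) {
    sprintf("%s* = %s", net@genes[i], net@rules[[i]]@text)
  }, character(1)), collapse = "\n")
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Export a network as a signed edge-list TSV
#'
#' @param net a [BooleanNetwork-class] with a populated edge list.
#' @param file output path.
#' @return the edge data.frame, invisibly.
#' @export
writeNetworkEdges <- function(net, file) {
  e <- networkEdges(net)
  utils::write.table(e[c("source", "target", "sign")], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(e)
}

#' Export a network as a JSON descriptor
#'
#' Serializes gene order, signed edges and per-gene rule text, so a network
#' artifact can be archived alongside the state vectors it indexes.
#'
#' @param net a [BooleanNetwork-class].
#' @param file optional output path.
#' @return JSON string (invisibly when `file` is set).
#' @export
networkToJSON <- function(net, file = NULL) {
  obj <- list(
    genes = networkGenes(net),
    edges = networkEdges(net),
    rules = as.list(ruleText(net))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(js, file)
    return(invisible(js))
  }
  js
}
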