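test_that("pathway genes are kept iff measured in either cell line", {
  tum <- matrix(1, 2, 1, dimnames = list(c("G1", "G3"), "t"))
  ctl <- matrix(1, 1, 1, dimnames = list("G3", "c"))
  res <- selectExpressedPathwayGenes(list(p = c("G1", "G2", "G3")), tum, ctl)
  expect_setequal(res$genes, c("G1", "G3"))
  expect_identical(res$perPathway$excluded, 1L)
  expect_warning(
    selectExpressedPathwayGenes(list(p = "Z9"), tum, ctl),
    "no gene in the expression data")
  expect_error(selectExpressedPathwayGenes(list(p = "G1"), tum[0, , drop = FALSE], ctl),
               "non-empty")
})

test_that("DE retention keeps up/down and defaults missing genes to ns", {
  de <- data.frame(gene = c("A", "B", "C"),
                   status = c("up", "ns", "down"))
  res <- retainDifferential(c("A", "B", "C"), de)
  expect_setequal(res$genes, c("A", "C"))
  expect_identical(unname(res$counts), c(1L, 1L))
  expect_warning(res2 <- retainDifferential(c("A", "Z"), de),
                 "missing from the DE table")
  expect_identical(res2$genes, "A")
  expect_warning(retainDifferential("B", de), "no differentially expressed")
})

test_that("hub selection is boundary inclusive at the degree cutoff", {
  star <- function(center, k)
    igraph::graph_from_data_frame(
      data.frame(a = center, b = paste0(center, "_n", seq_len(k))),
      directed = FALSE)
  g <- igraph::disjoint_union(star("H50", 50), star("H49", 49),
                              star("C", 60))
  res <- selectHubs(c("H50", "H49", "C", "ABSENT"), g, minHubDegree = 50)
  expect_setequal(res$genes, c("H50", "C"))
  expect_identical(unname(res$degree["H49"]), 49L)
  expect_identical(unname(res$degree["ABSENT"]), 0L)
})

test_that("distinct-partner degree collapses evidence and counts self once", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "A", "A", "B"), b = c("B", "B", "A", "C")),
    directed = FALSE)
  deg <- distinctDegree(g)
  expect_identical(unname(deg["A"]), 2L)  # partners: B and itself
  expect_identical(unname(deg["B"]), 2L)  # partners: A and C
})

test_that("directly linked seeds gain no intermediary", {
  g <- igraph::graph_from_data_frame(data.frame(a = "A", b = "B"),
                                     directed = FALSE)
  expr <- matrix(5, 2, 1, dimnames = list(c("A", "B"), "ref"))
  res <- connectWithIntermediaries(c("A", "B"), g, expr,
                                   constructionConfig(lowExpressionThreshold = 1))
  expect_identical(sum(res$nodes$provenance == "intermediary"), 0L)
  expect_identical(nrow(res$unconnected), 0L)
})

test_that("paths beyond the intermediary bound leave the pair unconnected", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "X", "Y", "Z", "W"),
               b = c("X", "Y", "Z", "W", "B")), directed = FALSE)
  genes <- c("A", "B", "X", "Y", "Z", "W")
  expr <- matrix(5, length(genes), 1, dimnames = list(genes, "ref"))
  res <- connectWithIntermediaries(c("A", "B"), g, expr,
                                   constructionConfig(maxIntermediaries = 3,
                                                      lowExpressionThreshold = 1))
  expect_identical(nrow(res$unconnected), 1L)
  # the same path is admitted once four internal vertices are allowed
  res4 <- connectWithIntermediaries(c("A", "B"), g, expr,
                                    constructionConfig(maxIntermediaries = 4,
                                                       lowExpressionThreshold = 1))
  expect_identical(nrow(res4$unconnected), 0L)
  expect_setequal(res4$nodes$node[res4$nodes$provenance == "intermediary"],
                  c("X", "Y", "Z", "W"))
})

test_that("low-expression intermediaries are rejected, expressed ones admitted", {
  g <- igraph::graph_from_data_frame(
    data.frame(a = c("A", "X"), b = c("X", "B")), directed = FALSE)
  expr <- matrix(c(5, 5, 5), 3, 1, dimnames = list(c("A", "B", "X"), "ref"))
  cfg <- constructionConfig(lowExpressionThreshold = 1)
  ok <- connectWithIntermediaries(c("A", "B"), g, expr, cfg)
  expect_identical(ok$nodes$node[ok$nodes$provenance == "intermediary"], "X")

  expr["X", ] <- 0.5
  rejected <- connectWithIntermediaries(c("A", "B"), g, expr, cfg)
  expect_identical(nrow(rejected$unconnected), 1L)
})

test_that("admitted paths match exhaustive simple-path enumeration on toy graphs", {
  set.seed(41)
  for (rep in 1:10) {
    nV <- 10
    vs <- c("A", "B", paste0("I", 1:(nV - 2)))
    el <- t(combn(vs, 2))
    keep <- runif(nrow(el)) < 0.25
    if (!any(keep)) next
    g <- igraph::graph_from_data_frame(as.data.frame(el[keep, , drop = FALSE]),
                                       directed = FALSE, vertices = vs)
    if (igraph::are_adjacent(g, "A", "B")) next
    expr <- matrix(runif(nV, 0, 10), nV, 1, dimnames = list(vs, "ref"))
    cfg <- constructionConfig(maxIntermediaries = 3,
                              lowExpressionThreshold = 2)
    res <- connectWithIntermediaries(c("A", "B"), g, expr, cfg)
    admissible <- setdiff(vs[expr[, 1] > 2], c("A", "B"))
    oracle <- enumerateAdmissiblePaths(g, "A", "B", admissible, 3)
    if (is.null(oracle)) {
      expect_identical(nrow(res$unconnected), 1L)
    } else {
      expect_identical(nrow(res$unconnected), 0L)
      got <- res$nodes$node[res$nodes$provenance == "intermediary"]
      expect_setequal(got, strsplit(oracle[1], ",")[[1]])
    }
  }
})

test_that("TF enrichment is the relational join on current vertices", {
  tf <- data.frame(tf = c("T1", "T2"), target = c("G", "Z9"),
                   mode = c("activation", "repression"))
  res <- enrichTranscriptionFactors("G", tf)
  expect_identical(res$nodes$node, "T1")
  expect_identical(res$edges$source, "T1")
  expect_identical(res$edges$sign, "activation")

  set.seed(43)
  tfs <- paste0("T", 1:12)
  targets <- paste0("G", 1:30)
  tab <- data.frame(tf = sample(tfs, 40, replace = TRUE),
                    target = sample(targets, 40, replace = TRUE),
                    mode = sample(c("activation", "repression", "unknown"),
                                  40, replace = TRUE))
  tab <- tab[!duplicated(tab[1:2]), ]
  vertices <- sample(targets, 12)
  res2 <- enrichTranscriptionFactors(vertices, tab)
  expect_setequal(res2$nodes$node,
                  setdiff(unique(tab$tf[tab$target %in% vertices]), vertices))
  expect_identical(nrow(res2$edges), sum(tab$target %in% vertices))
})

test_that("assembly builds frozen inputs and signed canalyzing rules", {
  sub <- list(
    nodes = data.frame(node = c("T", "G"), provenance = c("tf_table", "seed"),
                       degree = c(0L, 5L)),
    edges = data.frame(source = "T", target = "G", directed = TRUE,
                       sign = "activation", provenance = "tf_table"))
  asm <- assembleNetwork(sub, data.frame(source = character(),
                                         target = character(),
                                         sign = character()))
  expect_identical(unname(ruleText(asm$network)), c("T", "T"))
  expect_identical(asm$report$frozenInputs, 1L)

  sub2 <- list(
    nodes = data.frame(node = c("G", "A", "B"),
                       provenance = "seed", degree = c(1L, 2L, 3L)),
    edges = data.frame(source = c("A", "B"), target = c("G", "G"),
                       directed = TRUE, sign = NA_character_,
                       provenance = "interactome"))
  signs <- data.frame(source = c("A", "B"), target = c("G", "G"),
                      sign = c("activation", "inhibition"))
  asm2 <- assembleNetwork(sub2, signs)
  expect_identical(unname(ruleText(asm2$network)["G"]), "not B and A")
})

test_that("unsigned edges error, or default to activation when configured", {
  sub <- list(
    nodes = data.frame(node = c("A", "G"), provenance = "seed",
                       degree = c(1L, 1L)),
    edges = data.frame(source = "A", target = "G", directed = TRUE,
                       sign = NA_character_, provenance = "interactome"))
  noSigns <- data.frame(source = character(), target = character(),
                        sign = character())
  expect_error(assembleNetwork(sub, noSigns), "A->G")
  asm <- assembleNetwork(sub, noSigns,
                         constructionConfig(unsignedPolicy = "activation"))
  expect_identical(unname(ruleText(asm$network)["G"]), "A")
})

test_that("the construction fixture reproduces its hand-computed stage counts", {
  fx <- syntheticConstructionInputs()
  gt <- fx$groundTruth

  # every stage recomputed independently with set/graph arithmetic
  measured <- union(rownames(fx$tumorExpr), rownames(fx$controlExpr))
  expect_identical(
    vapply(fx$pathways, function(p) length(intersect(p, measured)), integer(1)),
    gt$retainedPerPathway)
  expect_setequal(
    fx$de$gene[fx$de$status %in% c("up", "down")], gt$deRetained)
  expect_identical(distinctDegree(fx$interactome, names(gt$hubDegrees)),
                   gt$hubDegrees)

  cn <- suppressWarnings(constructNetwork(
    fx$pathways, fx$tumorExpr, fx$controlExpr, fx$de, fx$interactome,
    fx$tfTable, fx$signTable, fx$config))
  expect_identical(cn$report$pathwayRetained, length(gt$pathwayGenes))
  expect_identical(cn$report$deRetained, length(gt$deRetained))
  expect_identical(cn$report$hubs, length(gt$hubs))
  expect_identical(cn$report$intermediaries, length(gt$intermediaries))
  expect_identical(cn$report$tfs, length(gt$tfs))
  expect_identical(cn$report$unconnectedPairs, gt$unconnectedPairs)
  expect_identical(networkSize(cn$network), gt$nGenes)
  expect_setequal(networkGenes(cn$network),
                  c(gt$seeds, gt$intermediaries, gt$tfs))
})

test_that("construction stages are monotone and deterministic", {
  fx <- syntheticConstructionInputs()
  run <- function() suppressWarnings(constructNetwork(
    fx$pathways, fx$tumorExpr, fx$controlExpr, fx$de, fx$interactome,
    fx$tfTable, fx$signTable, fx$config))
  a <- run(); b <- run()
  expect_identical(writeRules(a$network), writeRules(b$network))

  # filters never add; augmenters never remove
  pw <- selectExpressedPathwayGenes(fx$pathways, fx$tumorExpr, fx$controlExpr)
  de <- retainDifferential(pw$genes, fx$de)
  expect_true(all(de$genes %in% pw$genes))
  hubs <- selectHubs(de$genes, fx$interactome, fx$config$minHubDegree)
  expect_true(all(hubs$genes %in% de$genes))
  seeds <- sort(unique(c(hubs$genes, fx$config$seedGenes)))
  sub <- connectWithIntermediaries(seeds, fx$interactome, fx$tumorExpr,
                                   fx$config)
  expect_true(all(seeds %in% sub$nodes$node))
  tf <- enrichTranscriptionFactors(sub$nodes$node, fx$tfTable)
  expect_true(all(sub$nodes$node %in% c(sub$nodes$node, tf$nodes$node)))

  # every edge of the final network carries exactly one sign
  e <- networkEdges(a$network)
  expect_true(all(e$sign %in% c("activation", "inhibition")))
  expect_false(anyDuplicated(e[c("source", "target")]) > 0)
})

test_that("interactome readers parse MITAB and TSV with direction flags", {
  mitab <- tempfile(fileext = ".txt")
  writeLines(c(
    paste(c("uniprotkb:P1", "uniprotkb:P2", "-", "-",
            "psi-mi:p1(display_short)|uniprotkb:GENE1(gene name)",
            "psi-mi:p2(display_short)|uniprotkb:GENE2(gene name)",
            rep("-", 9)), collapse = "\t"),
    paste(c("uniprotkb:P1", "uniprotkb:P3", "-", "-",
            "uniprotkb:GENE1(gene name)", "uniprotkb:GENE3(gene name)",
            rep("-", 9)), collapse = "\t")), mitab)
  g <- readInteractome(mitab)
  expect_setequal(igraph::V(g)$name, c("GENE1", "GENE2", "GENE3"))
  expect_identical(unname(distinctDegree(g, "GENE1")), 2L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb\tdirected", "X\tY\tTRUE", "Y\tZ\tFALSE"), tsv)
  g2 <- readInteractome(tsv)
  expect_true(igraph::is_directed(g2))
  expect_identical(unname(distinctDegree(g2, "Y")), 2L)
})
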