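mkAttractor <- function(states) {
  tr <- NULL
  # build through the public path: a network is not needed, only the
  # canonical container; reuse simulateToAttractor on a crafted network
  # would be roundabout, so construct via new() like the package does.
  new("Attractor", states = states, period = length(states),
      kind = if (length(states) == 1L) "singleton" else "cyclic")
}

test_that("gene constancy labels follow the cycle fraction", {
  cyc <- mkAttractor(list(c(1L, 0L), c(1L, 1L)))
  expect_identical(labelGeneConstancy(cyc, 1)$label, "True")
  expect_identical(labelGeneConstancy(cyc, 2)$label, "X")

  # six distinct states (index bits), one constant-off gene, one gene on
  # in five of six states
  six <- mkAttractor(lapply(1:6, function(i)
    c(as.integer(intToBits(i))[1:3], 0L, as.integer(i <= 5))))
  expect_identical(labelGeneConstancy(six, 5, cycleFraction = 0.8)$label,
                   "True")
  expect_identical(labelGeneConstancy(six, 5, cycleFraction = 1)$label, "X")
  expect_equal(labelGeneConstancy(six, 5)$fraction, 5 / 6)
  expect_identical(labelGeneConstancy(six, 4)$label, "False")
})

test_that("labels partition: every (cell, gene) gets exactly one label", {
  net <- randomNCFNetwork(6, seed = 61)
  set.seed(62)
  for (rep in 1:20) {
    a <- trajectoryAttractor(simulateToAttractor(net, randomState(6)))
    labs <- vapply(1:6, function(g) labelGeneConstancy(a, g)$label,
                   character(1))
    expect_true(all(labs %in% c("True", "False", "X")))
  }
})

test_that("grouping drops pooled cells and partitions the rest", {
  ann <- data.frame(
    cell_id = c("c1", "c2", "c3"),
    sample_id = "S1",
    cell_type = c("malignant", "stromal", "malignant"),
    pooled = c(FALSE, FALSE, TRUE))
  g <- suppressMessages(groupCells(ann))
  expect_identical(nrow(g), 2L)
  expect_identical(sort(unique(g$group)),
                   c("S1|malignant", "S1|stromal"))
  expect_identical(sum(attr(g, "groupSizes")), 2L)

  bad <- data.frame(cell_id = "c1", sample_id = "", cell_type = "stromal")
  expect_error(groupCells(bad), "unknown sample id")
})

test_that("the default study profile reproduces its group sizes exactly", {
  sim <- simulateExpressionMatrix(expressionSimParams(nGenes = 3), seed = 2)
  g <- groupCells(sim$annotations)
  prof <- defaultGroupProfile()
  want <- setNames(prof$n, paste(prof$sample_id, prof$cell_type, sep = "|"))
  got <- attr(g, "groupSizes")
  expect_identical(got[sort(names(want))], want[sort(names(want))])
  expect_identical(sum(got), 549L)
  expect_identical(length(unique(sim$annotations$sample_id)), 14L)
})

test_that("the 95% consensus boundary is inclusive", {
  labels <- matrix("True", 20, 1, dimnames = list(NULL, "g"))
  labels[1, 1] <- "X"       # 19/20 = exactly 95%
  res <- consensusGenes(labels, minCellFraction = 0.95)
  expect_identical(res$label, "True")
  expect_equal(res$supportFraction, 0.95)

  labels[2, 1] <- "X"       # 18/20 = 90%: below threshold
  res2 <- consensusGenes(labels, minCellFraction = 0.95)
  expect_identical(res2$label, "X")
})

test_that("consensus equals brute-force counting on random label sets", {
  set.seed(71)
  for (rep in 1:25) {
    nc <- sample(5:40, 1)
    ng <- sample(2:8, 1)
    labels <- matrix(sample(c("True", "False", "X"), nc * ng, TRUE,
                            prob = c(.6, .25, .15)),
                     nc, ng, dimnames = list(NULL, paste0("g", 1:ng)))
    thr <- sample(c(0.8, 0.9, 0.95, 1), 1)
    res <- consensusGenes(labels, thr)
    expect_identical(res$label, unname(bruteConsensus(labels, thr)))
  }
})

test_that("raising the consensus threshold never creates a call", {
  set.seed(72)
  labels <- matrix(sample(c("True", "False", "X"), 30 * 5, TRUE),
                   30, 5, dimnames = list(NULL, paste0("g", 1:5)))
  lo <- consensusGenes(labels, 0.8)
  hi <- consensusGenes(labels, 0.95)
  called <- hi$label != "X"
  expect_true(all(lo$label[called] == hi$label[called]))
  expect_true(all(lo$label != "X" | hi$label == "X"))
})

test_that("duplicating every cell leaves the consensus unchanged", {
  set.seed(73)
  labels <- matrix(sample(c("True", "False", "X"), 12 * 4, TRUE),
                   12, 4, dimnames = list(NULL, paste0("g", 1:4)))
  once <- consensusGenes(labels, 0.9)
  twice <- consensusGenes(rbind(labels, labels), 0.9)
  expect_identical(once$label, twice$label)
  expect_equal(once$supportFraction, twice$supportFraction)
})

test_that("no-result cells leave the denominator", {
  labels <- matrix("True", 21, 1, dimnames = list(NULL, "g"))
  labels[1, ] <- NA  # a no-result cell: 20 attractor-bearing remain
  labels[2, 1] <- "X"
  res <- consensusGenes(labels, 0.95)
  expect_identical(attr(res, "nCells"), 20L)
  expect_identical(attr(res, "nNoResult"), 1L)
  expect_identical(res$label, "True")  # 19/20
  allNA <- matrix(NA_character_, 2, 1, dimnames = list(NULL, "g"))
  expect_error(consensusGenes(allNA), "empty")
})

test_that("strict settings mean constant-on in every state of every cell", {
  net <- randomNCFNetwork(5, seed = 81)
  set.seed(82)
  attrs <- lapply(1:15, function(i)
    trajectoryAttractor(simulateToAttractor(net, randomState(5))))
  labels <- do.call(rbind, lapply(attrs, function(a)
    vapply(1:5, function(g) labelGeneConstancy(a, g, 1)$label, character(1))))
  colnames(labels) <- networkGenes(net)
  res <- consensusGenes(labels, minCellFraction = 1)
  for (j in seq_len(5)) {
    allOn <- all(vapply(attrs, function(a)
      all(vapply(attractorStates(a), `[`, integer(1), j) == 1L), logical(1)))
    expect_identical(res$label[j] == "True", allOn)
  }
})

test_that("cross-group summary flags subtype-wide silence", {
  tabs <- list(
    "S1|malignant" = data.frame(gene = c("g1", "g2"),
                                label = c("False", "True"),
                                supportFraction = 1),
    "S2|malignant" = data.frame(gene = c("g1", "g2"),
                                label = c("False", "X"),
                                supportFraction = c(1, 0.6)),
    "S3|malignant" = data.frame(gene = c("g1", "g2"),
                                label = c("True", "True"),
                                supportFraction = 1))
  subtypes <- c("S1|malignant" = "TNBC", "S2|malignant" = "TNBC",
                "S3|malignant" = "LumA")
  res <- summarizeAcrossGroups(tabs, panel = c("g1", "g2"), subtypes)
  expect_identical(res$matrix["g1", "S1|malignant"], "constant_false")
  expect_identical(res$matrix["g2", "S2|malignant"], "non_constant")
  expect_true("never expressed in subtype TNBC" %in%
                res$patterns$g1$notes)
  expect_true(any(grepl("expressed in all groups except",
                        res$patterns$g2$notes)))
  expect_error(summarizeAcrossGroups(tabs, panel = "absent"),
               "absent")
})

test_that("summary cells equal direct lookups into the consensus tables", {
  set.seed(91)
  for (rep in 1:10) {
    genes <- paste0("g", 1:6)
    tabs <- setNames(lapply(1:4, function(i) {
      data.frame(gene = genes,
                 label = sample(c("True", "False", "X"), 6, TRUE),
                 supportFraction = 1)
    }), paste0("S", 1:4, "|malignant"))
    res <- summarizeAcrossGroups(tabs, panel = genes)
    for (g in names(tabs)) {
      lab <- setNames(tabs[[g]]$label, tabs[[g]]$gene)
      expect_identical(unname(res$matrix[, g]),
                       unname(ifelse(lab == "True", "constant_true",
                              ifelse(lab == "False", "constant_false",
                                     "non_constant"))[genes]))
    }
  }
})
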