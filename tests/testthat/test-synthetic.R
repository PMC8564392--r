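test_that("expression simulation is a pure function of (params, seed)", {
  p <- expressionSimParams(nGenes = 1,
                           groupProfile = data.frame(
                             sample_id = "S1", subtype = "TNBC",
                             cell_type = "malignant", n = 6L),
                           highProb = 0.5, dropoutRate = 0)
  a <- simulateExpressionMatrix(p, seed = 7)
  b <- simulateExpressionMatrix(p, seed = 7)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
  d <- simulateExpressionMatrix(p, seed = 8)
  expect_false(identical(a$expr, d$expr))
})

test_that("the noise-free limit returns the component means", {
  p <- expressionSimParams(nGenes = 4,
                           groupProfile = data.frame(
                             sample_id = "S1", subtype = "HER2",
                             cell_type = "malignant", n = 10L),
                           lowMean = 2, highMean = 8, sd = 1e-9,
                           highProb = 0.5, dropoutRate = 0)
  sim <- simulateExpressionMatrix(p, seed = 3)
  want <- ifelse(sim$truth == 1L, 8, 2)
  expect_equal(unname(sim$expr), unname(want), tolerance = 1e-6)
})

test_that("annotations follow the requested group profile", {
  sim <- simulateExpressionMatrix(expressionSimParams(nGenes = 2), seed = 5)
  prof <- defaultGroupProfile()
  got <- table(paste(sim$annotations$sample_id, sim$annotations$cell_type,
                     sep = "|"))
  want <- setNames(prof$n, paste(prof$sample_id, prof$cell_type, sep = "|"))
  expect_identical(as.integer(got[names(want)]), unname(want))
  expect_identical(ncol(sim$expr), 549L)
  expect_true(all(sim$expr >= 0))
  expect_error(expressionSimParams(
    nGenes = 2, groupProfile = data.frame(sample_id = "S", subtype = "x",
                                          cell_type = "malignant", n = 0L)))
})

test_that("random canalyzing networks are reproducible and well formed", {
  one <- randomNCFNetwork(1, seed = 4)
  expect_identical(networkGenes(one), "G001")
  expect_true(unname(ruleText(one)) %in% c("G001", "not G001"))

  a <- writeRules(randomNCFNetwork(12, seed = 10))
  b <- writeRules(randomNCFNetwork(12, seed = 10))
  expect_identical(a, b)

  # every generated rule is canalyzing: the first inhibitor at 1 forces 0
  for (s in 1:10) {
    net <- randomNCFNetwork(6, seed = 400 + s)
    for (r in networkRules(net)) {
      if (r@meta$type != "ncf" || !length(r@meta$inhibitors)) next
      k <- length(r@regulators)
      grid <- expand.grid(rep(list(0:1), k))
      names(grid) <- r@regulators
      for (row in seq_len(nrow(grid))) {
        st <- unlist(grid[row, , drop = FALSE])
        if (st[[r@meta$inhibitors[1]]] == 1L)
          expect_identical(evaluateRule(r, st), 0L)
      }
    }
  }
})

test_that("planted fixed points close under one update and are reachable", {
  p <- plantFixedPoint(plantedNetworkSpec(nGenes = 30, seed = 6))
  expect_identical(synchronousStep(p$network, p$targetState),
                   p$targetState)
  tr <- simulateToAttractor(p$network, p$targetState)
  a <- trajectoryAttractor(tr)
  expect_identical(attractorKind(a), "singleton")
  expect_identical(attractorKey(a), attractorKey(p$attractor))
})

test_that("states agreeing on the frozen inputs stay in the planted basin", {
  p <- plantFixedPoint(plantedNetworkSpec(nGenes = 25, seed = 9))
  nIn <- length(p$inputGenes)
  set.seed(10)
  hits <- 0L
  for (rep in 1:100) {
    st <- p$targetState
    free <- seq.int(nIn + 1L, length(st))
    st[free] <- randomState(length(free))
    a <- trajectoryAttractor(simulateToAttractor(p$network, st))
    if (attractorKey(a) == attractorKey(p$attractor)) hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("infeasible planted specs are refused", {
  # a target-1 gene with every input off cannot be activated
  expect_error(
    plantFixedPoint(plantedNetworkSpec(
      nGenes = 5, nInputs = 2,
      targetState = c(0L, 0L, 1L, 0L, 0L), seed = 1)),
    "infeasible")
})

test_that("well-separated mixtures are recovered end to end", {
  p <- expressionSimParams(
    nGenes = 20,
    groupProfile = data.frame(sample_id = "S1", subtype = "TNBC",
                              cell_type = "malignant", n = 120L),
    lowMean = 2, highMean = 8, sd = 0.5, highProb = 0.5, dropoutRate = 0)
  sim <- simulateExpressionMatrix(p, seed = 13)
  bin <- binarizeMatrix(sim$expr)
  expect_gte(mean(bin$bits == sim$truth), 0.99)
})

test_that("the simulated study writes the pipeline's input formats", {
  p <- expressionSimParams(nGenes = 4,
                           groupProfile = data.frame(
                             sample_id = "S1", subtype = "LumB",
                             cell_type = "malignant", n = 5L),
                           highProb = 0.5)
  sim <- simulateExpressionMatrix(p, seed = 2)
  dir <- tempfile("study")
  paths <- writeSimulatedStudy(sim, dir, network = randomNCFNetwork(4))
  expr <- readExpressionTable(paths[["expression"]])
  expect_equal(unname(expr), unname(sim$expr), tolerance = 1e-6)
  ann <- readCellAnnotations(paths[["annotations"]])
  expect_identical(ann$cell_id, sim$annotations$cell_id)
  net <- parseRules(readLines(paths[["rules"]]))
  expect_identical(networkSize(net), 4L)
})
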