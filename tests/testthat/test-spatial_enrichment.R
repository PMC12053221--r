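test_that("spatial QC keeps boundary cells and demands expression", {
  cells <- data.frame(cell_id = c("c1", "c2", "c3"), x = 1:3, y = 1:3,
                      sample_id = "s", condition = "PD",
                      label = "MOL", stringsAsFactors = FALSE)
  expr <- Matrix::Matrix(0, 12, 3, sparse = TRUE,
                         dimnames = list(sprintf("g%d", 1:12),
                                         c("c1", "c2", "c3")))
  expr[1:10, 1] <- 4       # 40 counts, 10 genes: kept
  expr[1:10, 2] <- 3.9     # 39 counts: removed
  expr[1:12, 3] <- 10      # well above: kept
  kept <- spatialQc(cells, expr)
  expect_identical(kept$cell_id, c("c1", "c3"))
  keptAll <- spatialQc(cells[3, ], expr)
  expect_identical(nrow(keptAll), 1L)
  expect_error(spatialQc(cells, NULL), "no expression")
})

test_that("radius graph respects the boundary, samples, and a brute force check", {
  cells <- data.frame(cell_id = sprintf("c%d", 1:4),
                      x = c(0, 100, 124.0001, 0), y = c(0, 0, 0, 0),
                      sample_id = c("s1", "s1", "s1", "s2"),
                      stringsAsFactors = FALSE)
  e <- radiusGraph(cells, 124)
  key <- paste(e$i, e$j)
  expect_true("1 2" %in% key)        # 100 um: edge
  expect_false("1 3" %in% key)       # 124.0001 um: no edge
  expect_false("1 4" %in% key)       # same spot, different sample: no edge
  expect_true("2 3" %in% key)        # 24 um
  expect_error(radiusGraph(cells, 0), "positive")

  set.seed(14)
  cl <- data.frame(cell_id = sprintf("r%d", 1:300),
                   x = runif(300, 0, 500), y = runif(300, 0, 500),
                   sample_id = sample(c("a", "b"), 300, TRUE),
                   stringsAsFactors = FALSE)
  e2 <- radiusGraph(cl, 60)
  brute <- list()
  for (i in 1:299) for (j in (i + 1):300) {
    if (cl$sample_id[i] == cl$sample_id[j] &&
        sqrt((cl$x[i] - cl$x[j])^2 + (cl$y[i] - cl$y[j])^2) <= 60)
      brute[[length(brute) + 1]] <- c(i, j)
  }
  bruteKey <- sort(vapply(brute, paste, character(1), collapse = " "))
  expect_identical(sort(paste(e2$i, e2$j)), bruteKey)
})

test_that("neighborhood z matches the exhaustive-arrangement oracle", {
  # 6-node path graph with a mixed label vector
  edges <- data.frame(i = 1:5, j = 2:6)
  attr(edges, "radius") <- 1
  labels <- c("A", "A", "B", "B", "C", "C")
  ex <- exhaustiveNhoodZ(edges, labels)
  nPerm <- 4000
  enr <- neighborhoodEnrichment(edges, labels, nPerm = nPerm, seed = 3)
  z <- enrichmentZ(enr)
  for (a in rownames(z)) for (b in colnames(z)) {
    if (ex$sd[a, b] == 0) next
    tol <- 3 * sqrt((1 + ex$z[a, b]^2 / 2) / nPerm) + 0.05
    expect_lt(abs(z[a, b] - ex$z[a, b]), tol)
  }
  expect_true(isSymmetric(z))
})

test_that("disjoint spatial blocks give positive diagonal, negative cross z", {
  set.seed(6)
  n <- 400
  cells <- data.frame(
    cell_id = sprintf("c%d", 1:n),
    x = c(runif(n / 2, 0, 400), runif(n / 2, 600, 1000)),
    y = runif(n, 0, 400),
    sample_id = "s1",
    label = rep(c("L1", "L2"), each = n / 2), stringsAsFactors = FALSE)
  enr <- neighborhoodEnrichment(radiusGraph(cells, 124), cells$label,
                                nPerm = 300, seed = 6)
  z <- enrichmentZ(enr)
  expect_gt(z["L1", "L1"], 0)
  expect_gt(z["L2", "L2"], 0)
  expect_lt(z["L1", "L2"], 0)
})

test_that("degenerate and null cases behave as declared", {
  edges <- data.frame(i = 1, j = 2)
  attr(edges, "radius") <- 1
  enr <- neighborhoodEnrichment(edges, c("A", "A"), nPerm = 50, seed = 1)
  expect_identical(unname(enrichmentZ(enr)), matrix(0))
  expect_true(enr@degenerate[1, 1])
  expect_error(neighborhoodEnrichment(edges, c("A", "B"), nPerm = 5), "nPerm")

  # calibration: under label shuffling the z-scores are unbiased, so the
  # per-pair z averaged over shuffle replicates shrinks toward zero (any one
  # replicate's |z| is a draw from roughly |N(0,1)|)
  set.seed(15)
  cells <- data.frame(cell_id = sprintf("c%d", 1:500),
                      x = runif(500, 0, 800), y = runif(500, 0, 800),
                      sample_id = "s1",
                      label = sample(c("A", "B", "C"), 500, TRUE),
                      stringsAsFactors = FALSE)
  g <- radiusGraph(cells, 124)
  zs <- lapply(1:12, function(r)
    enrichmentZ(neighborhoodEnrichment(g, sample(cells$label),
                                       nPerm = 300, seed = r)))
  zbar <- Reduce(`+`, zs) / length(zs)
  expect_lt(mean(abs(zbar[upper.tri(zbar, diag = TRUE)])), 0.5)
})

test_that("module scores capture planted condition shifts", {
  set.seed(4)
  expr <- matrix(rpois(50 * 60, 5), nrow = 50,
                 dimnames = list(sprintf("g%d", 1:50), sprintf("c%d", 1:60)))
  exprM <- Matrix::Matrix(expr, sparse = TRUE)
  s1 <- moduleScore(exprM, "g1")
  norm <- as.matrix(striatoglia::normalizeCounts(exprM["g1", , drop = FALSE]))
  expect_equal(unname(s1), unname((norm[1, ] - mean(norm[1, ])) / sd(norm[1, ])),
               tolerance = 1e-12)

  exprZ <- exprM
  exprZ["g2", ] <- 0
  expect_warning(moduleScore(exprZ, c("g1", "g2")), "zero-variance")
  expect_error(moduleScore(exprM, character()), "empty module")

  sp <- generateSpatial(spatialConfig(seed = 10, nCells = 600))
  kept <- spatialQc(sp$cells, sp$expr)
  ms <- moduleScore(sp$expr[, kept$cell_id], sp$truth$moduleGenes)
  expect_gt(mean(ms[kept$condition == "PD"]),
            mean(ms[kept$condition == "Control"]))
  cmp <- compareModuleScores(ms, kept$condition)
  expect_lt(cmp$p_value, 0.001)
  expect_identical(cmp$direction, 1)
})

test_that("module-score comparison matches exact small-sample enumeration", {
  set.seed(8)
  s <- rnorm(8)
  cond <- rep(c("Control", "PD"), each = 4)
  res <- compareModuleScores(s, cond)
  pExact <- wilcox.test(s[cond == "PD"], s[cond == "Control"],
                        exact = TRUE)$p.value
  expect_lt(abs(res$p_value - pExact), 0.02)
  expect_error(compareModuleScores(s, rep("PD", 8)), "Control")

  # planted 1-sd shift at n = 500 per condition is decisive
  set.seed(9)
  s2 <- c(rnorm(500), rnorm(500, 1))
  res2 <- compareModuleScores(s2, rep(c("Control", "PD"), each = 500))
  expect_lt(res2$p_value, 0.001)
})
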