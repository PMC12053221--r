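test_that("consensus doublet rule uses a strict more-than fraction", {
  calls <- rbind(rep(c(TRUE, FALSE), c(11, 89)),
                 rep(c(TRUE, FALSE), c(10, 90)))
  rownames(calls) <- c("a", "b")
  flag <- consensusDoubletFilter(calls, frac = 0.10)
  expect_identical(unname(flag), c(TRUE, FALSE))
  expect_error(consensusDoubletFilter(matrix(logical(), 2, 0)), "one run")
  callsNA <- calls; callsNA[1, 1] <- NA
  expect_error(consensusDoubletFilter(callsNA), "ragged")
})

test_that("hard thresholds flag the documented boundaries and keep edges", {
  meta <- data.frame(
    nucleus_id = sprintf("n%d", 1:6),
    n_umi      = c(499, 500, 250001, 5000, 5000, 5000),
    n_genes    = c(2000, 1200, 2000, 15001, 2000, 2000),
    mito_frac  = c(0.05, 0.10, 0.05, 0.05, 0.100001, 0.05))
  flag <- basicThresholdFilter(meta)
  expect_identical(unname(flag), c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE))
  expect_error(basicThresholdFilter(meta[, 1:2]), "missing field")
})

test_that("polynomial outlier filter flags linear-scale deviations from the fit", {
  # nuclei exactly on a quadratic log-log curve
  umi <- round(10^seq(3, 4.5, length.out = 40))
  lx <- log10(umi + 1)
  genes <- round(10^(0.2 + 0.9 * lx - 0.02 * lx^2) - 1)
  meta <- data.frame(nucleus_id = sprintf("n%d", seq_along(umi)),
                     n_umi = umi, n_genes = genes)
  expect_identical(sum(polynomialOutlierFilter(meta)), 0L)

  metaOut <- meta
  metaOut$n_genes[10] <- metaOut$n_genes[10] + 5000
  flag <- polynomialOutlierFilter(metaOut)
  expect_true(flag[10])
  expect_lt(sum(flag), 3)  # the plant, not the bulk

  expect_error(polynomialOutlierFilter(meta[1:3, ]), "at least 4")
  metaConst <- meta; metaConst$n_umi <- 1000
  expect_error(polynomialOutlierFilter(metaConst), "zero variance")
})

test_that("type scores separate classes and degrade gracefully", {
  m <- Matrix::sparseMatrix(
    i = c(1, 2, 3), j = c(1, 1, 2), x = c(5, 5, 7), dims = c(4, 3),
    dimnames = list(c("MK1", "MK2", "OT1", "OT2"), c("c1", "c2", "c3")))
  panel <- list(A = c("MK1", "MK2"), B = "OT1")
  sc <- computeTypeScores(m, panel)
  expect_equal(sc["c3", ], c(A = 0, B = 0))           # zero-count nucleus
  expect_gt(sc["c1", "A"], sc["c1", "B"])             # own marker dominates
  expect_gt(sc["c2", "B"], sc["c2", "A"])
  expect_error(computeTypeScores(m, list(A = "MISSING")), "no markers")

  sce <- sharedCohort()
  panelFull <- S4Vectors::metadata(sce)$panel
  gt <- S4Vectors::metadata(sce)$groundTruth
  singlet <- !gt$is_doublet
  scores <- computeTypeScores(sce[, singlet], panelFull)
  for (cls in names(panelFull)) {
    inCls <- gt$true_class[singlet] == cls
    expect_gt(mean(scores[inCls, cls]), mean(scores[!inCls, cls]))
  }
})

test_that("mixture threshold recovers the planted lower component", {
  set.seed(123)
  x <- c(rnorm(10000, 0, 1), rnorm(10000, 8, 1))
  th <- fitBimodalThreshold(x, className = "sim", seed = 1)
  expect_true(th@converged)
  expect_lt(abs(scoreThreshold(th) - 4), 0.15)
  expect_lt(abs(th@muLow), 0.1)
  expect_lt(abs(th@sigmaLow - 1), 0.1)

  # multiplier 0 returns the lower mean itself
  th0 <- fitBimodalThreshold(x, multiplier = 0, className = "sim", seed = 1)
  expect_equal(scoreThreshold(th0), th0@muLow)

  # unimodal scores: not converged, threshold +Inf
  thU <- fitBimodalThreshold(rnorm(5000), className = "uni", seed = 1)
  expect_false(thU@converged)
  expect_identical(scoreThreshold(thU), Inf)

  expect_error(fitBimodalThreshold(rnorm(10)), "at least 20")
  expect_error(fitBimodalThreshold(rep(1, 50)), "identical")
})

test_that("mixture parameters agree with an independent EM implementation", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))
  set.seed(42)
  x <- c(rnorm(3000, 1, 0.5), rnorm(1500, 5, 0.8))
  th <- fitBimodalThreshold(x, className = "x", seed = 1)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  muRef <- min(mc$parameters$mean)
  sdRef <- sqrt(mc$parameters$variance$sigmasq[which.min(mc$parameters$mean)])
  expect_lt(abs(th@muLow - muRef), 0.05)
  expect_lt(abs(th@sigmaLow - sdRef), 0.05)
})

test_that("multi-type rule flags only nuclei above two or more thresholds", {
  scores <- rbind(n1 = c(A = 5, B = 0.1), n2 = c(A = 5, B = 5),
                  n3 = c(A = 0.1, B = 0.1))
  thr <- c(A = 1, B = 1)
  flag <- multitypeDoubletFilter(scores, thr)
  expect_identical(unname(flag), c(FALSE, TRUE, FALSE))
  expect_error(multitypeDoubletFilter(scores, c(A = 1)), "missing for class")
})

test_that("regional contamination and gene prevalence rules honor boundaries", {
  m <- Matrix::sparseMatrix(i = c(1, 1, 2, 3), j = c(1, 3, 3, 4),
                            x = c(1, 2, 1, 1), dims = c(4, 4),
    dimnames = list(c("NEUROD2", "CARTPT", "G1", "G2"),
                    sprintf("n%d", 1:4)))
  flag <- regionalContaminationFilter(m, minCount = 1)
  expect_identical(unname(flag), c(TRUE, FALSE, TRUE, FALSE))
  flag3 <- regionalContaminationFilter(m, minCount = 3)
  expect_identical(unname(flag3), c(FALSE, FALSE, TRUE, FALSE))
  expect_error(regionalContaminationFilter(m[3:4, ]), "none of the regional")

  prev <- Matrix::sparseMatrix(i = c(1, 1, 2, 2, 2), j = c(1, 2, 1, 2, 3),
                               x = 1, dims = c(3, 3),
                               dimnames = list(c("gA", "gB", "gC"), NULL))
  keep <- genePrevalenceFilter(prev, minCells = 3)
  expect_identical(unname(keep), c(FALSE, TRUE, FALSE))
})

test_that("cascade is conservative, ordered, and idempotent where deterministic", {
  qc <- sharedQc()
  rep_ <- qc$report
  st <- qcStages(rep_)
  expect_identical(rep_@nInput - sum(st$n_flagged_new), rep_@nOutput)
  expect_true(all(diff(st$n_remaining) <= 0))
  expect_identical(st$stage[2:3], c("hard_thresholds", "polynomial_outliers"))

  # deterministic stages flag nothing on their own output
  sceF <- qc$sce
  mdF <- as.data.frame(SummarizedExperiment::colData(sceF))
  mdF$nucleus_id <- colnames(sceF)
  expect_identical(sum(basicThresholdFilter(mdF)), 0L)
  if (any(regionalMarkers() %in% rownames(sceF))) {
    expect_identical(sum(regionalContaminationFilter(sceF)), 0L)
  } else {
    # all contaminated nuclei were removed, so the regional markers fell
    # below the prevalence cutoff and left the matrix entirely
    expect_error(regionalContaminationFilter(sceF), "none of the regional")
  }
  expect_identical(sum(!genePrevalenceFilter(sceF)), 0L)

  # raising min_umi never decreases the hard-threshold flag count
  md <- as.data.frame(SummarizedExperiment::colData(sharedCohort()))
  md$nucleus_id <- rownames(md)
  nFlag <- vapply(c(200, 500, 1000, 3000), function(mu)
    sum(basicThresholdFilter(md, qcConfig(minUmi = mu))), integer(1))
  expect_true(all(diff(nFlag) >= 0))
})

test_that("a cascade with all thresholds disabled is the identity", {
  cfgOff <- qcConfig(minUmi = -Inf, minGenes = -Inf, maxUmi = Inf,
                     maxGenes = Inf, maxMitoFrac = Inf,
                     residThresholdGenes = Inf, gmmSdMultiplier = 1e9,
                     minMarkerCountRegional = Inf, minCellsPerGene = 0)
  sce <- generateCohort(smallSynthConfig())
  res <- runQcCascade(sce, S4Vectors::metadata(sce)$panel, cfgOff, seed = 1)
  expect_identical(ncol(res$sce), ncol(sce))
  expect_identical(nrow(res$sce), nrow(sce))
  expect_true(all(qcStages(res$report)$n_flagged_new == 0))
})
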