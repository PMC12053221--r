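test_that("cohort generation is deterministic and sample streams are stable", {
  a <- generateCohort(smallSynthConfig())
  b <- generateCohort(smallSynthConfig())
  expect_identical(as.matrix(SummarizedExperiment::assay(a)),
                   as.matrix(SummarizedExperiment::assay(b)))
  expect_identical(S4Vectors::metadata(a)$groundTruth,
                   S4Vectors::metadata(b)$groundTruth)

  # adding a sample leaves existing samples' draws untouched
  cfg3 <- smallSynthConfig()
  cfg3$samples <- rbind(cfg3$samples,
                        data.frame(sample_id = "C1", condition = "PD",
                                   region = "CN", sex = "M", n_nuclei = 50L))
  c3 <- generateCohort(cfg3)
  shared <- colnames(a)
  expect_identical(as.matrix(SummarizedExperiment::assay(c3)[, shared]),
                   as.matrix(SummarizedExperiment::assay(a)))
})

test_that("planted anomaly counts follow the configured rates", {
  cfg <- smallSynthConfig()
  cfg$doubletRate <- 0
  gt <- S4Vectors::metadata(generateCohort(cfg))$groundTruth
  expect_identical(sum(gt$is_doublet), 0L)

  cfg2 <- synthConfig(
    seed = 5, nGenes = 600,
    samples = data.frame(sample_id = c("A1", "A2"),
                         condition = c("Control", "PD"), region = c("CN", "Pu"),
                         sex = c("M", "F"), n_nuclei = 500L),
    doubletRate = 0.1, outlierGeneOffset = 300L)
  gt2 <- S4Vectors::metadata(generateCohort(cfg2))$groundTruth
  n <- nrow(gt2)
  expect_identical(n, 1000L)
  # expected 100 +- binomial noise; the flag count IS the drawn truth
  expect_lt(abs(sum(gt2$is_doublet) - 100), 4 * sqrt(1000 * 0.1 * 0.9))
  # doublets record exactly two distinct source classes
  dd <- gt2[gt2$is_doublet, ]
  expect_true(all(!is.na(dd$doublet_class_2)))
  expect_true(all(dd$doublet_class_1 != dd$doublet_class_2))
})

test_that("config validation rejects inconsistent settings", {
  cfg <- smallSynthConfig()
  cfg$classes$propControl[1] <- cfg$classes$propControl[1] + 0.05
  expect_error(generateCohort(cfg), "sum to 1")
  expect_error(synthConfig(nGenes = 50), "smaller than total markers")
  expect_error(synthConfig(doubletRate = 1.4), "doubletRate")
})

test_that("library sizes match the lognormal target and anomalies are recoverable", {
  cfg <- synthConfig(
    seed = 9, nGenes = 600,
    samples = data.frame(sample_id = "A1", condition = "Control",
                         region = "CN", sex = "M", n_nuclei = 1200L),
    doubletRate = 0, contaminantRate = 0.1, outlierRate = 0,
    depthLogMean = log(3000), depthLogSd = 0.3)
  sce <- generateCohort(cfg)
  md <- as.data.frame(SummarizedExperiment::colData(sce))
  gt <- S4Vectors::metadata(sce)$groundTruth
  target <- exp(log(3000) + 0.3^2 / 2)
  expect_lt(abs(mean(md$n_umi) - target), 3 * sd(md$n_umi) / sqrt(nrow(md)))
  # every contaminant carries at least one regional-marker count
  counts <- SummarizedExperiment::assay(sce)
  regTot <- Matrix::colSums(counts[regionalMarkers(), ])
  expect_true(all(regTot[gt$is_contaminant] >= 1))
})

test_that("spatial generator plants co-localization only when bands exist", {
  cfgU <- spatialConfig(seed = 4, nCells = 400, bandLabels = character())
  spU <- generateSpatial(cfgU)
  expect_identical(nrow(spU$truth$colocalizedPairs), 0L)

  sp <- generateSpatial(spatialConfig(seed = 4, nCells = 600))
  band <- sp$cells$label %in% c("MOL", "PDAO")
  expect_true(all(sp$cells$x[band] <= 300))
  expect_identical(sp$truth$colocalizedPairs, cbind("MOL", "PDAO"),
                   ignore_attr = TRUE)
  # planted band self-adjacency exceeds the label-permuted expectation
  kept <- sp$cells
  edges <- radiusGraph(kept, 124)
  enr <- neighborhoodEnrichment(edges, kept$label, nPerm = 200, seed = 4)
  expect_gt(enrichmentZ(enr)["MOL", "MOL"], 0)
})

test_that("GSEA fixture plants enrichment and Jaccard block structure", {
  fx0 <- generateGseaFixture(gseaConfig(seed = 6, shift = 0))
  expect_length(fx0$truth$enriched, 0)

  fx <- generateGseaFixture(gseaConfig(seed = 6))
  blockSets <- fx$sets[names(fx$truth$blockMembership)]
  J <- jaccardMatrix(blockSets)
  for (b in unique(fx$truth$blockMembership)) {
    inB <- names(fx$truth$blockMembership)[fx$truth$blockMembership == b]
    expect_true(all(J[inB, inB] >= 0.8))
    outB <- setdiff(rownames(J), inB)
    expect_true(all(J[inB, outB] <= 0.1))
  }
  # the planted set attains the largest ES among all sets
  es <- prerankedGsea(fx$ranked, fx$sets, nPerm = 20, seed = 6)
  expect_true(es$pathway[which.max(es$ES)] %in% fx$truth$enriched)
  expect_error(gseaConfig(blockOverlap = 60, setSize = 50), "cannot exceed")
})

test_that("ROI generator plants the configured associations", {
  samples <- data.frame(sample_id = sprintf("D%02d", 1:10),
                        condition = rep(c("Control", "PD"), 5),
                        region = "Pu", ratio = seq(0.2, 2, length.out = 10))
  roi <- generateRoiTable(roiConfig(seed = 2, slope = -0.1, noiseSd = 0,
                                    conditionOffset = c(Control = 0, PD = 0)),
                          samples)
  ints <- roi[roi$measurement_type == "mean_dab_intensity", ]
  expect_equal(spearmanTest(samples$ratio,
                            ints$value[match(samples$sample_id,
                                             ints$donor_id)])$rho, -1)

  roiFlat <- generateRoiTable(roiConfig(seed = 2, slope = 0, noiseSd = 0.02,
                                        conditionOffset = c(Control = 0, PD = 0)),
                              samples)
  intsF <- roiFlat[roiFlat$measurement_type == "mean_dab_intensity", ]
  expect_lt(abs(spearmanTest(samples$ratio,
                             intsF$value[match(samples$sample_id,
                                               intsF$donor_id)])$rho), 0.8)

  # planted Control > PD separation in the area marker gives a positive t
  summ <- summarizeDonor(generateRoiTable(roiConfig(seed = 2), samples))
  area <- summ[summ$marker == "TH", ]
  tt <- twoSampleT(area$pct_positive[area$condition == "Control"],
                   area$pct_positive[area$condition == "PD"])
  expect_gt(tt$t, 0)
  expect_error(generateRoiTable(roiConfig(), samples[, 1:3]), "columns")
})
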