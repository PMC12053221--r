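#' Canonical striatal cell-type marker panel
#'
#' The glial/neuronal marker genes used for type scoring and annotation:
#' oligodendrocytes (MBP, MOG, MAG), OPCs (PTPRZ1, PDGFRA, VCAN), astrocytes
#' (AQP4, ADGRV1), microglia (CSF1R, FYB1), vascular cells (EBF1, ABCB1,
#' ABCA9) and neurons (MEG3).
#'
#' @return Named list mapping class name to marker gene ids.
#' @export
canonicalMarkerPanel <- function() {
  list(
    Oligodendrocytes = c("MBP", "MOG", "MAG"),
    OPCs             = c("PTPRZ1", "PDGFRA", "VCAN"),
    Astrocytes       = c("AQP4", "ADGRV1"),
    Microglia        = c("CSF1R", "FYB1"),
    Vascular         = c("EBF1", "ABCB1", "ABCA9"),
    Neurons          = c("MEG3")
  )
}

#' Regional contamination marker genes
#'
#' Markers of neighboring regions (claustrum/amygdala); nuclei expressing
#' them are treated as regional contamination.
#'
#' @return Character vector of gene ids.
#' @export
regionalMarkers <- function() c("NEUROD2", "TMEM155", "CARTPT", "SLC17A7")

#' Synthetic-cohort configuration
#'
#' Defaults describe the simulated study cohort: ten donors (five Control,
#' five PD) split across caudate nucleus and putamen, 500 nuclei each
#' (5,000 total), six striatal cell classes with 25 markers at fold-change 8,
#' lognormal library depth, negative-binomial counts, and planted anomalies:
#' 10\% doublets, 5\% regional contaminants, 2\% gene~UMI outliers, and a 2\%
#' tail of nuclei with mitochondrial fraction above 0.10.
#'
#' @param seed integer RNG seed; identical configs give identical cohorts.
#' @param nGenes number of genes simulated.
#' @param classes data.frame with columns `name`, `propControl`, `propPD`,
#'   `nMarkers`, `foldChange`; per-condition proportions must each sum to 1.
#' @param samples data.frame with columns `sample_id`, `condition`, `region`,
#'   `sex`, `n_nuclei`.
#' @param depthLogMean,depthLogSd lognormal library-size parameters.
#' @param doubletRate,contaminantRate,outlierRate planted anomaly fractions.
#' @param mitoFracMean mean of the (beta-distributed) bulk mitochondrial
#'   fraction; `mitoTailFrac` of nuclei instead draw uniformly from
#'   (0.10, `mitoTailMax`).
#' @param mitoTailFrac,mitoTailMax high-mitochondrial tail parameters.
#' @param dispersion negative-binomial dispersion; variance = mu + mu^2/dispersion.
#' @param outlierGeneOffset number of extra single-count genes added to each
#'   planted outlier, breaking the gene~UMI relationship.
#' @param exprGeneFrac fraction of genes given non-trivial baseline expression.
#' @return A `synthConfig` list.
#' @export
synthConfig <- function(seed = 1L,
                        nGenes = 6000L,
                        classes = NULL,
                        samples = NULL,
                        depthLogMean = log(5000),
                        depthLogSd = 0.3,
                        doubletRate = 0.10,
                        contaminantRate = 0.05,
                        outlierRate = 0.02,
                        mitoFracMean = 0.04,
                        mitoTailFrac = 0.02,
                        mitoTailMax = 0.25,
                        dispersion = 2,
                        outlierGeneOffset = 5000L,
                        exprGeneFrac = 0.4) {
  if (is.null(classes)) {
    classes <- data.frame(
      name = c("Oligodendrocytes", "OPCs", "Astrocytes", "Microglia",
               "Neurons", "Vascular"),
      propControl = c(0.40, 0.14, 0.14, 0.12, 0.12, 0.08),
      propPD      = c(0.36, 0.14, 0.14, 0.12, 0.16, 0.08),
      nMarkers = 25L, foldChange = 8,
      stringsAsFactors = FALSE)
  }
  if (is.null(samples)) {
    samples <- data.frame(
      sample_id = sprintf("S%02d", 1:10),
      condition = rep(c("Control", "PD"), each = 5),
      region = rep(c("CN", "Pu"), 5),
      sex = rep(c("M", "F"), 5),
      n_nuclei = 500L,
      stringsAsFactors = FALSE)
  }
  cfg <- list(seed = as.integer(seed), nGenes = as.integer(nGenes),
              classes = classes, samples = samples,
              depthLogMean = depthLogMean, depthLogSd = depthLogSd,
              doubletRate = doubletRate, contaminantRate = contaminantRate,
              outlierRate = outlierRate, mitoFracMean = mitoFracMean,
              mitoTailFrac = mitoTailFrac, mitoTailMax = mitoTailMax,
              dispersion = dispersion,
              outlierGeneOffset = as.integer(outlierGeneOffset),
              exprGeneFrac = exprGeneFrac)
  class(cfg) <- c("synthConfig", "list")
  .validateSynthConfig(cfg)
  cfg
}

.validateSynthConfig <- function(cfg) {
  cl <- cfg$classes
  if (abs(sum(cl$propControl) - 1) > 1e-9 || abs(sum(cl$propPD) - 1) > 1e-9)
    stop("class proportions must sum to 1 per condition", call. = FALSE)
  for (r in c("doubletRate", "contaminantRate", "outlierRate",
              "mitoTailFrac", "exprGeneFrac"))
    .assertScalarNumeric(cfg[[r]], r, 0, 1)
  nMarkersTotal <- sum(cl$nMarkers) + length(regionalMarkers())
  if (cfg$nGenes < nMarkersTotal)
    stop(sprintf("nGenes (%d) smaller than total markers requested (%d)",
                 cfg$nGenes, nMarkersTotal), call. = FALSE)
  if (cfg$doubletRate + cfg$contaminantRate + cfg$outlierRate > 1)
    stop("anomaly rates sum above 1", call. = FALSE)
  invisible(cfg)
}

# Gene universe: class markers (canonical names first), regional markers
# (near-zero baseline), then filler genes. Class expression profiles are
# gamma-weighted over an "expressed" subset; markers are up-shifted by the
# class fold-change in their own class only.
.buildGeneModel <- function(cfg) {
  set.seed(deriveSeed(cfg$seed, "profiles"))
  cl <- cfg$classes
  panelCanon <- canonicalMarkerPanel()
  geneIds <- character(cfg$nGenes)
  markerIdx <- list()
  pos <- 1L
  for (i in seq_len(nrow(cl))) {
    n <- cl$nMarkers[i]
    canon <- panelCanon[[cl$name[i]]] %||% character()
    canon <- head(canon, n)
    abbrev <- toupper(substr(gsub("[^A-Za-z]", "", cl$name[i]), 1, 3))
    extra <- sprintf("%sM%02d", abbrev, seq_len(n - length(canon)))
    ids <- c(canon, extra)[seq_len(n)]
    geneIds[pos:(pos + n - 1L)] <- ids
    markerIdx[[cl$name[i]]] <- pos:(pos + n - 1L)
    pos <- pos + n
  }
  regIdx <- pos:(pos + length(regionalMarkers()) - 1L)
  geneIds[regIdx] <- regionalMarkers()
  pos <- pos + length(regionalMarkers())
  fill <- pos:cfg$nGenes
  geneIds[fill] <- sprintf("G%05d", seq_along(fill))

  nExpr <- max(round(cfg$exprGeneFrac * cfg$nGenes), sum(cl$nMarkers))
  # expressed set always contains the markers; fill the rest from filler genes
  exprIdx <- c(unlist(markerIdx, use.names = FALSE),
               fill[seq_len(max(0L, nExpr - sum(cl$nMarkers)))])
  base <- rep(1e-4, cfg$nGenes)
  base[exprIdx] <- stats::rgamma(length(exprIdx), shape = 2, rate = 1)
  base[regIdx] <- 1e-6
  profiles <- matrix(base, nrow = cfg$nGenes, ncol = nrow(cl),
                     dimnames = list(geneIds, cl$name))
  for (i in seq_len(nrow(cl)))
    profiles[markerIdx[[cl$name[i]]], i] <-
      profiles[markerIdx[[cl$name[i]]], i] * cl$foldChange[i]
  profiles <- sweep(profiles, 2, colSums(profiles), "/")
  panel <- lapply(markerIdx, function(ix) geneIds[ix])
  list(geneIds = geneIds, profiles = profiles, panel = panel,
       regionalIdx = regIdx)
}

#' Generate a synthetic single-nucleus cohort with planted ground truth
#'
#' Draws per-nucleus negative-binomial counts around class expression
#' profiles scaled by a lognormal library depth. Planted anomalies:
#' doublets are the sum of two full, independently drawn nuclei of distinct
#' classes; contaminants carry counts in the regional marker genes; outliers
#' get `outlierGeneOffset` extra single-count genes so their detected-gene
#' count breaks the gene~UMI curve. Per-sample RNG sub-streams are derived by
#' stable hashing of the sample id, so adding a sample leaves the others
#' untouched.
#'
#' @param cfg a [synthConfig()].
#' @return A [SingleCellExperiment::SingleCellExperiment] with assay `counts`,
#'   per-nucleus colData (`sample_id`, `condition`, `region`, `sex`, `n_umi`,
#'   `n_genes`, `mito_frac`) and `metadata()` entries `groundTruth`
#'   (per-nucleus `true_class`, `is_doublet`, doublet source classes,
#'   `is_contaminant`, `is_outlier`), `panel` (planted marker panel),
#'   `trueProportions`, and `config`.
#' @export
generateCohort <- function(cfg = synthConfig()) {
  .validateSynthConfig(cfg)
  gm <- .buildGeneModel(cfg)
  cl <- cfg$classes
  blocks <- vector("list", nrow(cfg$samples))
  metas <- vector("list", nrow(cfg$samples))
  truths <- vector("list", nrow(cfg$samples))
  for (s in seq_len(nrow(cfg$samples))) {
    sm <- cfg$samples[s, ]
    set.seed(deriveSeed(cfg$seed, sm$sample_id))
    n <- sm$n_nuclei
    props <- if (sm$condition == "PD") cl$propPD else cl$propControl
    status <- sample(c("singlet", "doublet", "contaminant", "outlier"), n,
                     replace = TRUE,
                     prob = c(1 - cfg$doubletRate - cfg$contaminantRate -
                                cfg$outlierRate,
                              cfg$doubletRate, cfg$contaminantRate,
                              cfg$outlierRate))
    class1 <- sample(cl$name, n, replace = TRUE, prob = props)
    class2 <- rep(NA_character_, n)
    mat <- matrix(0, nrow = cfg$nGenes, ncol = n)
    for (i in seq_len(n)) {
      depth <- rlnorm(1, cfg$depthLogMean, cfg$depthLogSd)
      x <- rnbinom(cfg$nGenes, mu = depth * gm$profiles[, class1[i]],
                   size = cfg$dispersion)
      if (status[i] == "doublet") {
        others <- setdiff(cl$name, class1[i])
        p2 <- props[match(others, cl$name)]
        class2[i] <- sample(others, 1, prob = p2 / sum(p2))
        depth2 <- rlnorm(1, cfg$depthLogMean, cfg$depthLogSd)
        x <- x + rnbinom(cfg$nGenes, mu = depth2 * gm$profiles[, class2[i]],
                         size = cfg$dispersion)
      } else if (status[i] == "contaminant") {
        add <- rpois(length(gm$regionalIdx), 1.0)
        if (sum(add) == 0) add[sample.int(length(add), 1)] <- 1L
        x[gm$regionalIdx] <- x[gm$regionalIdx] + add
      } else if (status[i] == "outlier") {
        zeros <- which(x == 0)
        k <- min(cfg$outlierGeneOffset, length(zeros))
        x[zeros[sample.int(length(zeros), k)]] <- 1
      }
      mat[, i] <- x
    }
    mito <- ifelse(runif(n) < cfg$mitoTailFrac,
                   runif(n, 0.10 + 1e-6, cfg$mitoTailMax),
                   rbeta(n, 2, 2 * (1 - cfg$mitoFracMean) / cfg$mitoFracMean))
    ids <- sprintf("%s_N%04d", sm$sample_id, seq_len(n))
    blocks[[s]] <- methods::as(Matrix::Matrix(mat, sparse = TRUE), "CsparseMatrix")
    metas[[s]] <- data.frame(
      nucleus_id = ids, sample_id = sm$sample_id, condition = sm$condition,
      region = sm$region, sex = sm$sex,
      n_umi = colSums(mat), n_genes = colSums(mat > 0), mito_frac = mito,
      stringsAsFactors = FALSE)
    truths[[s]] <- data.frame(
      nucleus_id = ids, true_class = class1,
      is_doublet = status == "doublet",
      doublet_class_1 = ifelse(status == "doublet", class1, NA_character_),
      doublet_class_2 = class2,
      is_contaminant = status == "contaminant",
      is_outlier = status == "outlier",
      stringsAsFactors = FALSE)
  }
  counts <- do.call(cbind, blocks)
  meta <- do.call(rbind, metas)
  truth <- do.call(rbind, truths)
  rownames(counts) <- gm$geneIds
  colnames(counts) <- meta$nucleus_id
  rownames(meta) <- meta$nucleus_id
  rownames(truth) <- truth$nucleus_id
  trueProps <- do.call(rbind, lapply(split(truth, meta$sample_id), function(tt)
    prop.table(table(factor(tt$true_class, levels = cl$name)))))
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(meta))
  S4Vectors::metadata(sce) <- list(groundTruth = truth, panel = gm$panel,
                                   trueProportions = trueProps, config = cfg)
  sce
}

#' Emulate per-run doublet-caller output for the consensus rule
#'
#' Produces a nuclei x runs logical call matrix in which planted doublets are
#' called positive in each run with probability `doubletCallRate` and other
#' nuclei with probability `falseCallRate`, emulating repeated runs of an
#' external doublet caller whose per-run calls feed the >10\%-of-runs
#' consensus rule.
#'
#' @param sce cohort from [generateCohort()] (ground truth in metadata).
#' @param runs number of emulated runs (default 100).
#' @param doubletCallRate per-run sensitivity for true doublets.
#' @param falseCallRate per-run false-positive rate for non-doublets.
#' @param seed RNG seed.
#' @return Logical matrix, nuclei x runs.
#' @export
generateDoubletCalls <- function(sce, runs = 100L, doubletCallRate = 0.3,
                                 falseCallRate = 0.02, seed = 1L) {
  truth <- S4Vectors::metadata(sce)$groundTruth
  stopifnot(!is.null(truth))
  set.seed(deriveSeed(seed, "doublet_calls"))
  p <- ifelse(truth$is_doublet, doubletCallRate, falseCallRate)
  calls <- matrix(runif(nrow(truth) * runs) < rep(p, runs),
                  nrow = nrow(truth), ncol = runs,
                  dimnames = list(truth$nucleus_id, NULL))
  calls
}

#' Spatial-map configuration
#'
#' Defaults emulate a white-matter tract: the `MOL` and `PDAO` labels are
#' confined to a vertical band of the tissue rectangle while other labels are
#' uniform, so band labels are mutually co-localized at the analysis radius.
#' A small panel-style expression matrix is attached, with a planted
#' PD-upshifted gene module and a fraction of low-quality cells.
#'
#' @param seed RNG seed.
#' @param nCells total cells across samples.
#' @param samples data.frame with `sample_id`, `condition`.
#' @param width,height field size in micrometres.
#' @param labels data.frame with `label`, `proportion` (summing to 1).
#' @param bandLabels labels confined to the band.
#' @param bandX numeric length-2 x-range of the band in micrometres.
#' @param nGenesPanel,panelDepth size/depth of the attached expression panel.
#' @param moduleSize,moduleShift planted module gene count and PD log-shift.
#' @param lowQualityFrac fraction of cells drawn with near-zero depth.
#' @return A `spatialConfig` list.
#' @export
spatialConfig <- function(seed = 1L, nCells = 2000L,
                          samples = data.frame(
                            sample_id = c("X1", "X2"),
                            condition = c("Control", "PD"),
                            stringsAsFactors = FALSE),
                          width = 1000, height = 1000,
                          labels = data.frame(
                            label = c("MOL", "PDAO", "OPC", "ASTRO"),
                            proportion = c(0.35, 0.15, 0.30, 0.20),
                            stringsAsFactors = FALSE),
                          bandLabels = c("MOL", "PDAO"),
                          bandX = c(0, 300),
                          nGenesPanel = 300L, panelDepth = 150,
                          moduleSize = 20L, moduleShift = 1,
                          lowQualityFrac = 0.05) {
  if (abs(sum(labels$proportion) - 1) > 1e-9)
    stop("label proportions must sum to 1", call. = FALSE)
  if (width <= 0 || height <= 0) stop("empty region", call. = FALSE)
  cfg <- list(seed = as.integer(seed), nCells = as.integer(nCells),
              samples = samples, width = width, height = height,
              labels = labels, bandLabels = bandLabels, bandX = bandX,
              nGenesPanel = as.integer(nGenesPanel), panelDepth = panelDepth,
              moduleSize = as.integer(moduleSize), moduleShift = moduleShift,
              lowQualityFrac = lowQualityFrac)
  class(cfg) <- c("spatialConfig", "list")
  cfg
}

#' Generate a synthetic spatial cell map with planted co-localization
#'
#' @param cfg a [spatialConfig()].
#' @return List with `cells` (data.frame `cell_id`, `x`, `y`, `sample_id`,
#'   `condition`, `label`), `expr` (panel genes x cells sparse counts), and
#'   `truth` (`colocalized` label pairs, `moduleGenes`, `lowQuality` flags).
#' @export
generateSpatial <- function(cfg = spatialConfig()) {
  nPer <- rep(floor(cfg$nCells / nrow(cfg$samples)), nrow(cfg$samples))
  nPer[1] <- nPer[1] + cfg$nCells - sum(nPer)
  allCells <- list(); allExpr <- list(); lowQ <- list()
  genes <- sprintf("P%03d", seq_len(cfg$nGenesPanel))
  moduleGenes <- genes[seq_len(cfg$moduleSize)]
  set.seed(deriveSeed(cfg$seed, "panel_weights"))
  w <- stats::rgamma(cfg$nGenesPanel, shape = 1.5, rate = 1)
  for (s in seq_len(nrow(cfg$samples))) {
    sm <- cfg$samples[s, ]
    set.seed(deriveSeed(cfg$seed, paste0("spatial_", sm$sample_id)))
    n <- nPer[s]
    lab <- sample(cfg$labels$label, n, replace = TRUE,
                  prob = cfg$labels$proportion)
    inBand <- lab %in% cfg$bandLabels
    x <- ifelse(inBand, runif(n, cfg$bandX[1], cfg$bandX[2]),
                runif(n, 0, cfg$width))
    y <- runif(n, 0, cfg$height)
    ids <- sprintf("%s_C%04d", sm$sample_id, seq_len(n))
    allCells[[s]] <- data.frame(cell_id = ids, x = x, y = y,
                                sample_id = sm$sample_id,
                                condition = sm$condition, label = lab,
                                stringsAsFactors = FALSE)
    ws <- w
    mod <- matrix(rep(ws, n), nrow = cfg$nGenesPanel)
    if (sm$condition == "PD")
      mod[match(moduleGenes, genes), ] <-
        mod[match(moduleGenes, genes), ] * exp(cfg$moduleShift)
    mod <- sweep(mod, 2, colSums(mod), "/")
    low <- runif(n) < cfg$lowQualityFrac
    depth <- ifelse(low, runif(n, 1, 25), cfg$panelDepth * rlnorm(n, 0, 0.25))
    cnt <- matrix(rpois(cfg$nGenesPanel * n, t(t(mod) * depth)),
                  nrow = cfg$nGenesPanel,
                  dimnames = list(genes, ids))
    allExpr[[s]] <- methods::as(Matrix::Matrix(cnt, sparse = TRUE),
                                "CsparseMatrix")
    lowQ[[s]] <- setNames(low, ids)
  }
  cells <- do.call(rbind, allCells)
  colocal <- if (length(cfg$bandLabels) && !setequal(cfg$bandLabels,
                                                    cfg$labels$label)) {
    t(combn(sort(cfg$bandLabels), 2))
  } else {
    matrix(character(), ncol = 2)
  }
  list(cells = cells, expr = do.call(cbind, allExpr),
       truth = list(colocalizedLabels = sort(unique(cfg$bandLabels)),
                    colocalizedPairs = colocal,
                    moduleGenes = moduleGenes,
                    lowQuality = unlist(lowQ)))
}

#' Preranked-GSEA fixture configuration
#'
#' @param seed RNG seed.
#' @param listLength number of ranked genes.
#' @param plantedSets number of gene sets whose members get the score shift.
#' @param nNullSets number of random unshifted sets.
#' @param setSize genes per set.
#' @param shift mean score shift added to planted-set members.
#' @param blocks,setsPerBlock,blockOverlap redundant-set block design for the
#'   Jaccard clustering fixture: each block holds `setsPerBlock` variants of a
#'   base set sharing `blockOverlap` of its `setSize` genes (pairwise Jaccard
#'   within block \eqn{\ge 0.8} for the defaults; blocks are disjoint).
#' @return A `gseaConfig` list.
#' @export
gseaConfig <- function(seed = 1L, listLength = 1000L, plantedSets = 2L,
                       nNullSets = 18L, setSize = 50L, shift = 2,
                       blocks = 2L, setsPerBlock = 3L, blockOverlap = 46L) {
  if (blockOverlap > setSize)
    stop("blockOverlap cannot exceed setSize", call. = FALSE)
  withinJ <- blockOverlap / (2 * setSize - blockOverlap)
  cfg <- list(seed = as.integer(seed), listLength = as.integer(listLength),
              plantedSets = as.integer(plantedSets),
              nNullSets = as.integer(nNullSets), setSize = as.integer(setSize),
              shift = shift, blocks = as.integer(blocks),
              setsPerBlock = as.integer(setsPerBlock),
              blockOverlap = as.integer(blockOverlap), withinJaccard = withinJ)
  class(cfg) <- c("gseaConfig", "list")
  cfg
}

#' Generate a ranked list, gene-set collection and planted truth for GSEA
#'
#' Scores are standard normal; members of planted sets are shifted upward so
#' those sets are enriched at the top of the ranking. Additional disjoint
#' blocks of near-duplicate sets provide a ground-truth clustering for the
#' superpathway Jaccard/linkage stage.
#'
#' @param cfg a [gseaConfig()].
#' @return List with `ranked` (data.frame `gene`, `score`, descending),
#'   `sets` (named list), and `truth` (`enriched` set names, `blockMembership`
#'   named vector over block sets).
#' @export
generateGseaFixture <- function(cfg = gseaConfig()) {
  set.seed(deriveSeed(cfg$seed, "gsea_fixture"))
  genes <- sprintf("RG%05d", seq_len(cfg$listLength))
  scores <- rnorm(cfg$listLength)
  sets <- list()
  planted <- character()
  used <- integer()
  for (i in seq_len(cfg$plantedSets)) {
    idx <- sample(setdiff(seq_len(cfg$listLength), used), cfg$setSize)
    used <- c(used, idx)
    nm <- sprintf("PLANTED_SET_%d", i)
    sets[[nm]] <- genes[idx]
    planted <- c(planted, nm)
    if (cfg$shift != 0) scores[idx] <- scores[idx] + cfg$shift
  }
  for (i in seq_len(cfg$nNullSets)) {
    idx <- sample(seq_len(cfg$listLength), cfg$setSize)
    sets[[sprintf("NULL_SET_%02d", i)]] <- genes[idx]
  }
  blockMembership <- integer()
  if (cfg$blocks > 0) {
    need <- cfg$blocks * (cfg$setSize + cfg$setsPerBlock *
                            (cfg$setSize - cfg$blockOverlap))
    pool <- sample(seq_len(cfg$listLength))
    if (need > cfg$listLength)
      stop("block design infeasible for the list length", call. = FALSE)
    at <- 1L
    for (b in seq_len(cfg$blocks)) {
      core <- pool[at:(at + cfg$blockOverlap - 1L)]
      at <- at + cfg$blockOverlap
      for (v in seq_len(cfg$setsPerBlock)) {
        fresh <- pool[at:(at + cfg$setSize - cfg$blockOverlap - 1L)]
        at <- at + cfg$setSize - cfg$blockOverlap
        nm <- sprintf("BLOCK%d_SET_%d", b, v)
        sets[[nm]] <- genes[c(core, fresh)]
        blockMembership[nm] <- b
      }
    }
  }
  ord <- order(scores, decreasing = TRUE)
  list(ranked = data.frame(gene = genes[ord], score = scores[ord],
                           stringsAsFactors = FALSE),
       sets = sets,
       truth = list(enriched = if (cfg$shift != 0) planted else character(),
                    blockMembership = blockMembership))
}

#' Histology ROI-table configuration
#'
#' @param seed RNG seed.
#' @param intercept,slope,noiseSd linear model for per-sample DAB intensity as
#'   a function of a subpopulation ratio; a negative slope plants a negative
#'   monotone association.
#' @param conditionOffset named numeric additive intensity offsets per
#'   condition.
#' @param marker intensity marker name (default "MBP").
#' @param areaMarker marker quantified as positive/total area (default "TH").
#' @param areaMeans,areaSds named per-condition mean/sd of the positive-area
#'   fraction for `areaMarker`.
#' @param roisPerDonor ROIs generated per donor for the area marker.
#' @param totalArea ROI total area in square micrometres.
#' @return A `roiConfig` list.
#' @export
roiConfig <- function(seed = 1L, intercept = 0.30, slope = -0.4,
                      noiseSd = 0.005,
                      conditionOffset = c(Control = 0, PD = -0.02),
                      marker = "MBP", areaMarker = "TH",
                      areaMeans = c(Control = 0.05, PD = 0.012),
                      areaSds = c(Control = 0.012, PD = 0.004),
                      roisPerDonor = 3L, totalArea = 1e6) {
  cfg <- list(seed = as.integer(seed), intercept = intercept, slope = slope,
              noiseSd = noiseSd, conditionOffset = conditionOffset,
              marker = marker, areaMarker = areaMarker,
              areaMeans = areaMeans, areaSds = areaSds,
              roisPerDonor = as.integer(roisPerDonor), totalArea = totalArea)
  class(cfg) <- c("roiConfig", "list")
  cfg
}

#' Generate a histology ROI measurement table tied to cohort composition
#'
#' Per-sample mean DAB intensity is `intercept + slope * ratio +
#' conditionOffset + noise`, so a negative slope plants the negative
#' ratio-vs-intensity association; the area marker gets per-ROI positive and
#' total areas whose per-condition means plant a group difference.
#'
#' @param cfg a [roiConfig()].
#' @param samples data.frame with columns `sample_id`, `condition`, `region`,
#'   and `ratio` (the subpopulation ratio driving intensity).
#' @return data.frame in the ROI-table layout of [tableSchema]`("roiTable")`.
#' @export
generateRoiTable <- function(cfg = roiConfig(), samples) {
  need <- c("sample_id", "condition", "region", "ratio")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(is.na(samples$ratio))) stop("missing samples (NA ratio)", call. = FALSE)
  set.seed(deriveSeed(cfg$seed, "roi_table"))
  intensity <- cfg$intercept + cfg$slope * samples$ratio +
    cfg$conditionOffset[samples$condition] +
    rnorm(nrow(samples), 0, cfg$noiseSd)
  rows <- data.frame(donor_id = samples$sample_id, region = samples$region,
                     condition = samples$condition, marker = cfg$marker,
                     measurement_type = "mean_dab_intensity",
                     value = pmax(intensity, 0), stringsAsFactors = FALSE)
  area <- do.call(rbind, lapply(seq_len(nrow(samples)), function(i) {
    frac <- pmin(pmax(rnorm(cfg$roisPerDonor,
                            cfg$areaMeans[samples$condition[i]],
                            cfg$areaSds[samples$condition[i]]), 0), 1)
    data.frame(donor_id = samples$sample_id[i], region = samples$region[i],
               condition = samples$condition[i], marker = cfg$areaMarker,
               measurement_type = rep(c("positive_area_um2", "total_area_um2"),
                                      each = cfg$roisPerDonor),
               value = c(frac * cfg$totalArea, rep(cfg$totalArea,
                                                   cfg$roisPerDonor)),
               stringsAsFactors = FALSE)
  }))
  rbind(rows, area)
}
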