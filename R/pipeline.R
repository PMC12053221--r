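#' Pipeline configuration
#'
#' One configuration object driving the full synthetic-cohort pipeline.
#' Per-stage RNG sub-seeds are derived from the global seed by stable
#' hashing of the stage name, so enabling or disabling a stage leaves the
#' other stages' random streams untouched.
#'
#' @param seed global integer seed.
#' @param stages named logical vector enabling stages, in dependency order
#'   `simulate`, `qc`, `annotate`, `compose`, `gsea`, `superpath`,
#'   `spatial`, `histo`.
#' @param synth,qc,gseaFixture,spatial,roi stage configuration objects;
#'   `NULL` means the stage default with a derived seed.
#' @param nPermGsea,nPermSpatial permutation counts.
#' @param ratioPops numerator/denominator subpopulations for the
#'   ratio-vs-intensity correlation.
#' @return A `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L,
                           stages = c(simulate = TRUE, qc = TRUE,
                                      annotate = TRUE, compose = TRUE,
                                      gsea = TRUE, superpath = TRUE,
                                      spatial = TRUE, histo = TRUE),
                           synth = NULL, qc = NULL, gseaFixture = NULL,
                           spatial = NULL, roi = NULL,
                           nPermGsea = 1000L, nPermSpatial = 1000L,
                           ratioPops = c("OPCs", "Oligodendrocytes")) {
  cfg <- list(seed = as.integer(seed), stages = stages,
              synth = synth %||% synthConfig(seed = deriveSeed(seed, "simulate")),
              qc = qc %||% qcConfig(),
              gseaFixture = gseaFixture %||%
                gseaConfig(seed = deriveSeed(seed, "gsea")),
              spatial = spatial %||%
                spatialConfig(seed = deriveSeed(seed, "spatial")),
              roi = roi %||% roiConfig(seed = deriveSeed(seed, "histo")),
              nPermGsea = as.integer(nPermGsea),
              nPermSpatial = as.integer(nPermSpatial),
              ratioPops = ratioPops)
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

.writeTsv <- function(df, path) {
  listCols <- vapply(df, is.list, logical(1))
  for (cl in names(df)[listCols])
    df[[cl]] <- vapply(df[[cl]], paste, character(1), collapse = ";")
  write.table(format(df, digits = 15, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.configHash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic-cohort pipeline
#'
#' Executes the enabled stages in dependency order — cohort simulation, QC
#' cascade, lineage annotation and marker ranking, compositional statistics,
#' preranked GSEA, superpathway aggregation, spatial neighborhood
#' enrichment and module scores, histology statistics — writing per-stage
#' tables under `outDir` and aggregating the headline results into
#' `report.json`, stamped with the configuration hash and seed. With
#' `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory.
#' @param resume skip stages whose marker outputs exist (default FALSE).
#' @return Invisibly, the report list.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir, resume = FALSE) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = config$seed, config_hash = .configHash(config),
                 warnings = list())
  on <- function(st) isTRUE(unname(config$stages[st]))
  done <- function(f) resume && file.exists(file.path(outDir, f))
  noteWarnings <- function(expr, stage) {
    withCallingHandlers(expr, warning = function(w) {
      report$warnings[[stage]] <<- c(report$warnings[[stage]],
                                     conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  sce <- NULL; qcOut <- NULL; labels <- NULL; comp <- NULL; roi <- NULL
  if (on("simulate") && !done("meta.tsv")) {
    sce <- generateCohort(config$synth)
    writeCounts(sce, file.path(outDir, "counts"))
    .writeTsv(as.data.frame(SummarizedExperiment::colData(sce)),
              file.path(outDir, "meta.tsv"))
  } else if (any(config$stages[-1])) {
    sce <- generateCohort(config$synth)  # deterministic regeneration
  }

  if (on("qc") && !is.null(sce)) {
    calls <- generateDoubletCalls(sce, seed = deriveSeed(config$seed, "qc"))
    qcOut <- noteWarnings(
      runQcCascade(sce, S4Vectors::metadata(sce)$panel, config$qc,
                   doubletCalls = calls,
                   seed = deriveSeed(config$seed, "qc")), "qc")
    .writeTsv(qcStages(qcOut$report), file.path(outDir, "qc_funnel.tsv"))
    flg <- qcOut$flags
    flg <- cbind(nucleus_id = rownames(flg), flg)
    .writeTsv(flg, file.path(outDir, "qc_flags.tsv"))
    nonConv <- names(qcOut$thresholds)[!vapply(qcOut$thresholds,
                                               function(t) t@converged,
                                               logical(1))]
    if (length(nonConv))
      report$warnings$qc <- c(report$warnings$qc,
                              paste("non-converged mixture for:",
                                    paste(nonConv, collapse = ", ")))
    report$qc <- list(
      n_input = qcOut$report@nInput, n_output = qcOut$report@nOutput,
      genes_removed = qcOut$report@genesRemoved,
      funnel = qcStages(qcOut$report))
  }

  if (on("annotate") && !is.null(qcOut)) {
    panel <- S4Vectors::metadata(sce)$panel
    labels <- noteWarnings(assignClasses(qcOut$sce, panel), "annotate")
    de <- rankMarkers(qcOut$sce, labels)
    markers <- noteWarnings(selectMarkers(de), "annotate")
    .writeTsv(data.frame(nucleus_id = names(labels), label = unname(labels)),
              file.path(outDir, "labels.tsv"))
    .writeTsv(de[de$p_value < 0.05 & de$log2_fc > 0.5, ],
              file.path(outDir, "markers.tsv"))
    prof <- subpopulationProfiles(qcOut$sce, labels)
    hc <- buildDendrogram(prof)
    dendrogramNewick(hc, file.path(outDir, "dendrogram.nwk"))
    report$annotation <- list(n_labeled = length(labels),
                              classes = sort(unique(unname(labels))),
                              n_markers = lengths(markers))
  }

  if (on("compose") && !is.null(labels)) {
    meta <- as.data.frame(SummarizedExperiment::colData(qcOut$sce))
    meta$label <- unname(labels[rownames(meta)])
    comp <- compositionTable(meta)
    .writeTsv(comp, file.path(outDir, "composition.tsv"))
    deltas <- do.call(rbind, lapply(intersect(c("CN", "Pu"),
                                              unique(meta$region)),
      function(rg) cbind(region = rg, conditionDelta(comp, rg))))
    .writeTsv(deltas, file.path(outDir, "deltas.tsv"))
    report$composition <- list(deltas = deltas)
  }

  gsea <- NULL
  if (on("gsea")) {
    fx <- generateGseaFixture(config$gseaFixture)
    gsea <- noteWarnings(
      prerankedGsea(fx$ranked, fx$sets, nPerm = config$nPermGsea,
                    seed = deriveSeed(config$seed, "gsea")), "gsea")
    gsea$contrast <- "synthetic_contrast"
    .writeTsv(gsea, file.path(outDir, "gsea_results.tsv"))
    report$gsea <- list(
      n_sets = nrow(gsea),
      n_enriched = nrow(filterEnriched(gsea)),
      top = gsea$pathway[which.max(gsea$NES)])
    if (on("superpath")) {
      merged <- mergeRedundant(gsea, fx$sets)
      J <- jaccardMatrix(fx$sets[merged$pathway])
      clusters <- clusterSuperpathways(J)
      super <- summarizeSuperpathways(clusters, merged, fx$sets)
      .writeTsv(super, file.path(outDir, "superpathways.tsv"))
      .writeTsv(cbind(pathway = rownames(J), as.data.frame(J)),
                file.path(outDir, "jaccard.tsv"))
      report$gsea$n_superpathways <- nrow(super)
    }
  }

  if (on("spatial")) {
    sp <- generateSpatial(config$spatial)
    kept <- spatialQc(sp$cells, sp$expr)
    edges <- radiusGraph(kept, radius = 124)
    enr <- neighborhoodEnrichment(edges, kept$label,
                                  nPerm = config$nPermSpatial,
                                  seed = deriveSeed(config$seed, "spatial"))
    zm <- enrichmentZ(enr)
    .writeTsv(cbind(label = rownames(zm), as.data.frame(zm)),
              file.path(outDir, "enrichment_z.tsv"))
    ms <- noteWarnings(
      moduleScore(sp$expr[, kept$cell_id], sp$truth$moduleGenes), "spatial")
    cmpM <- compareModuleScores(ms, kept$condition)
    .writeTsv(data.frame(cell_id = names(ms), score = unname(ms)),
              file.path(outDir, "module_scores.tsv"))
    report$spatial <- list(n_cells_kept = nrow(kept), z = zm,
                           module_p = cmpM$p_value,
                           module_direction = cmpM$direction)
  }

  if (on("histo")) {
    ratioTab <- NULL
    if (!is.null(comp)) {
      num <- comp[comp$subpopulation == config$ratioPops[1], ]
      den <- comp[comp$subpopulation == config$ratioPops[2], ]
      m <- merge(num[c("sample_id", "condition", "region", "pct_of_sample")],
                 den[c("sample_id", "pct_of_sample")],
                 by = "sample_id", suffixes = c("_num", "_den"))
      ratioTab <- data.frame(sample_id = m$sample_id,
                             condition = m$condition, region = m$region,
                             ratio = m$pct_of_sample_num / m$pct_of_sample_den,
                             stringsAsFactors = FALSE)
    } else {
      sm <- config$synth$samples
      set.seed(deriveSeed(config$seed, "histo_ratio"))
      ratioTab <- data.frame(sample_id = sm$sample_id,
                             condition = sm$condition, region = sm$region,
                             ratio = runif(nrow(sm), 0.2, 1),
                             stringsAsFactors = FALSE)
    }
    roi <- generateRoiTable(config$roi, ratioTab)
    .writeTsv(roi, file.path(outDir, "roi.csv"))
    summ <- summarizeDonor(roi)
    .writeTsv(summ, file.path(outDir, "donor_summaries.tsv"))
    intens <- summ[summ$marker == config$roi$marker, ]
    intensities <- setNames(intens$mean_intensity, intens$donor_id)
    corr <- if (!is.null(comp))
      ratioVsIntensity(comp, intensities, config$ratioPops[1],
                       config$ratioPops[2])
    else spearmanTest(ratioTab$ratio, intensities[ratioTab$sample_id])
    area <- summ[summ$marker == config$roi$areaMarker, ]
    tt <- twoSampleT(area$pct_positive[area$condition == "Control"],
                     area$pct_positive[area$condition == "PD"])
    tRecon <- tFromSummary(tt$means[1], tt$sems[1], tt$means[2], tt$sems[2])
    .writeTsv(data.frame(
      test = c("area_t_welch", "area_t_from_summary", "ratio_intensity_rho",
               "ratio_intensity_p"),
      value = c(tt$t, tRecon, corr$rho, corr$p_value)),
      file.path(outDir, "histology_tests.tsv"))
    report$histology <- list(area_t = tt$t, area_p = tt$p,
                             t_from_summary = tRecon,
                             ratio_intensity_rho = corr$rho,
                             ratio_intensity_p = corr$p_value)
  }

  reportJson <- report
  reportJson$qc$funnel <- if (!is.null(report$qc)) report$qc$funnel
  jsonlite::write_json(reportJson, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = 12, force = TRUE,
                       pretty = TRUE)
  invisible(report)
}
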