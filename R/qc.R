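#' Quality-control configuration
#'
#' Thresholds for the nuclei QC cascade. Defaults: nuclei flagged when called
#' a doublet in more than 10\% of external caller runs; fewer than 500 UMIs
#' or 1,200 genes; more than 250,000 UMIs, over 15,000 genes, or above 10\%
#' mitochondrial content; a detected-gene count deviating by more than 2,000
#' genes from a degree-2 polynomial fit of log10 genes on log10 UMIs; marker
#' scores above the mixture threshold (lower-component mean plus four of its
#' SDs) for two or more cell types; any expression of a regional
#' contamination marker; and genes detected in fewer than three nuclei.
#'
#' @param consensusFrac fraction of caller runs above which a nucleus is a
#'   consensus doublet (strictly more than).
#' @param minUmi,minGenes,maxUmi,maxGenes,maxMitoFrac hard thresholds;
#'   boundary values are retained.
#' @param polyDegree polynomial degree of the gene~UMI fit.
#' @param residThresholdGenes outlier residual threshold. By default the
#'   residual is measured on the linear detected-gene scale (the fitted
#'   log10 value is back-transformed before differencing); set
#'   `residOnLogScale = TRUE` to compare on the log10 scale instead.
#' @param residOnLogScale logical; see above.
#' @param gmmSdMultiplier number of lower-component SDs added to its mean.
#' @param minMarkerCountRegional summed regional-marker counts at or above
#'   which a nucleus is flagged as contamination.
#' @param minCellsPerGene gene prevalence threshold (kept when detected in at
#'   least this many nuclei).
#' @param targetSum library-size normalization target for type scores.
#' @return A `qcConfig` list.
#' @export
qcConfig <- function(consensusFrac = 0.10, minUmi = 500, minGenes = 1200,
                     maxUmi = 250000, maxGenes = 15000, maxMitoFrac = 0.10,
                     polyDegree = 2, residThresholdGenes = 2000,
                     residOnLogScale = FALSE, gmmSdMultiplier = 4,
                     minMarkerCountRegional = 1, minCellsPerGene = 3,
                     targetSum = 1e4) {
  cfg <- list(consensusFrac = consensusFrac, minUmi = minUmi,
              minGenes = minGenes, maxUmi = maxUmi, maxGenes = maxGenes,
              maxMitoFrac = maxMitoFrac, polyDegree = polyDegree,
              residThresholdGenes = residThresholdGenes,
              residOnLogScale = residOnLogScale,
              gmmSdMultiplier = gmmSdMultiplier,
              minMarkerCountRegional = minMarkerCountRegional,
              minCellsPerGene = minCellsPerGene, targetSum = targetSum)
  class(cfg) <- c("qcConfig", "list")
  cfg
}

#' Consensus doublet filter over repeated caller runs
#'
#' A nucleus is flagged when it was called a doublet in strictly more than
#' `frac` of the runs.
#'
#' @param calls logical matrix, nuclei x runs.
#' @param frac consensus fraction (default 0.10).
#' @return Named logical vector.
#' @export
consensusDoubletFilter <- function(calls, frac = 0.10) {
  if (is.null(dim(calls)) || ncol(calls) == 0L)
    stop("call matrix must have at least one run", call. = FALSE)
  if (any(is.na(calls)))
    stop("ragged call matrix: NA calls present", call. = FALSE)
  setNames(rowMeans(calls) > frac, rownames(calls))
}

#' Hard UMI / gene / mitochondrial threshold filter
#'
#' Flags nuclei with fewer than `minUmi` UMIs or `minGenes` genes, more than
#' `maxUmi` UMIs or `maxGenes` genes, or mitochondrial fraction exceeding
#' `maxMitoFrac`. Boundary values are retained.
#'
#' @param meta data.frame with `n_umi`, `n_genes`, `mito_frac`.
#' @param cfg a [qcConfig()].
#' @return Logical vector, named by `meta$nucleus_id` when present.
#' @export
basicThresholdFilter <- function(meta, cfg = qcConfig()) {
  need <- c("n_umi", "n_genes", "mito_frac")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(meta[need])))
    stop("metadata contains missing values in QC fields", call. = FALSE)
  flag <- meta$n_umi < cfg$minUmi | meta$n_genes < cfg$minGenes |
    meta$n_umi > cfg$maxUmi | meta$n_genes > cfg$maxGenes |
    meta$mito_frac > cfg$maxMitoFrac
  setNames(flag, meta$nucleus_id)
}

#' Polynomial gene~UMI outlier filter
#'
#' Fits detected genes against UMIs as a degree-`polyDegree` polynomial in
#' log10-log10 space on the nuclei provided, then flags nuclei whose
#' detected-gene count deviates from the back-transformed prediction by more
#' than `residThresholdGenes` genes (or, with `residOnLogScale`, whose log10
#' gene count deviates by more than the threshold on the log scale).
#'
#' @param meta data.frame with `n_umi`, `n_genes` for the surviving nuclei.
#' @param cfg a [qcConfig()].
#' @return Logical vector, named by `meta$nucleus_id` when present.
#' @export
polynomialOutlierFilter <- function(meta, cfg = qcConfig()) {
  n <- nrow(meta)
  if (n < cfg$polyDegree + 2)
    stop(sprintf("need at least %d nuclei for a degree-%d fit, got %d",
                 cfg$polyDegree + 2, cfg$polyDegree, n), call. = FALSE)
  lx <- log10(meta$n_umi + 1)
  ly <- log10(meta$n_genes + 1)
  if (var(lx) == 0) stop("zero variance in UMI counts", call. = FALSE)
  fit <- lm(ly ~ poly(lx, cfg$polyDegree, raw = TRUE))
  pred <- fit$fitted.values
  resid <- if (isTRUE(cfg$residOnLogScale)) abs(ly - pred)
           else abs(meta$n_genes - (10^pred - 1))
  setNames(resid > cfg$residThresholdGenes, meta$nucleus_id)
}

#' Per-nucleus cell-type scores from marker panels
#'
#' Score = mean, over the class's markers present in the matrix, of
#' library-size-normalized log1p expression.
#'
#' @param x cohort (`SingleCellExperiment`) or gene x nucleus count matrix.
#' @param panel named list mapping class name to marker gene ids.
#' @param targetSum normalization target (default 1e4).
#' @return Numeric matrix, nuclei x classes, with attribute `missingMarkers`.
#' @export
computeTypeScores <- function(x, panel, targetSum = 1e4) {
  counts <- .getCounts(x)
  if (!length(panel)) stop("empty marker panel", call. = FALSE)
  norm <- normalizeCounts(counts, targetSum = targetSum)
  missing <- list()
  scores <- matrix(0, ncol(counts), length(panel),
                   dimnames = list(colnames(counts), names(panel)))
  for (cls in names(panel)) {
    present <- intersect(panel[[cls]], rownames(counts))
    if (!length(present))
      stop(sprintf("class '%s' has no markers present in the matrix", cls),
           call. = FALSE)
    absent <- setdiff(panel[[cls]], present)
    if (length(absent)) missing[[cls]] <- absent
    sub <- norm[present, , drop = FALSE]
    scores[, cls] <- Matrix::colMeans(sub)
  }
  attr(scores, "missingMarkers") <- missing
  scores
}

# One EM pass for a univariate 2-component Gaussian mixture.
.emFit <- function(x, mu, sg, w, tol = 1e-6, maxIter = 500L) {
  n <- length(x)
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    d1 <- w * dnorm(x, mu[1], sg[1])
    d2 <- (1 - w) * dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    r <- d1 / tot
    llNew <- sum(log(tot))
    w <- mean(r)
    if (w < 1e-8 || w > 1 - 1e-8) return(NULL)  # component collapsed
    mu[1] <- sum(r * x) / sum(r)
    mu[2] <- sum((1 - r) * x) / sum(1 - r)
    sg[1] <- sqrt(sum(r * (x - mu[1])^2) / sum(r))
    sg[2] <- sqrt(sum((1 - r) * (x - mu[2])^2) / sum(1 - r))
    sg <- pmax(sg, 1e-8 * (max(x) - min(x)) + 1e-12)
    if (is.finite(ll) && abs(llNew - ll) < tol) break
    ll <- llNew
  }
  list(mu = mu, sg = sg, w = w, ll = llNew)
}

#' Fit a two-component Gaussian mixture and derive the score threshold
#'
#' Fits a univariate two-component Gaussian mixture by EM (quantile-based
#' initialization, `restarts` jittered restarts, fixed seed) and sets the
#' threshold at the mean of the lower-mean component plus `multiplier` of its
#' standard deviations. When the two components are indistinguishable
#' (|muHigh - muLow| below half the pooled sigma) the fit is reported
#' non-converged with threshold +Inf, so the downstream filter flags nothing.
#'
#' @param scores numeric vector of one class's per-nucleus scores (>= 20).
#' @param multiplier SD multiplier (default 4).
#' @param className class name carried into the result.
#' @param seed RNG seed for restart jitter.
#' @param restarts,tol,maxIter EM protocol parameters.
#' @return A [BimodalThreshold-class] object.
#' @export
fitBimodalThreshold <- function(scores, multiplier = 4, className = "class",
                                seed = 1L, restarts = 5L, tol = 1e-6,
                                maxIter = 500L) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 20)
    stop("need at least 20 finite scores", call. = FALSE)
  if (sd(scores) == 0) stop("all scores identical", call. = FALSE)
  set.seed(deriveSeed(seed, paste0("gmm_", className)))
  q <- quantile(scores, c(0.25, 0.75), names = FALSE)
  s0 <- sd(scores) / 2
  best <- NULL
  for (r in seq_len(restarts)) {
    mu0 <- if (r == 1) q else q + rnorm(2, 0, s0)
    fit <- .emFit(scores, mu = sort(mu0), sg = c(s0, s0), w = 0.5,
                  tol = tol, maxIter = maxIter)
    if (!is.null(fit) && (is.null(best) || fit$ll > best$ll)) best <- fit
  }
  if (is.null(best)) {
    return(new("BimodalThreshold", className = className, muLow = mean(scores),
               sigmaLow = sd(scores), muHigh = mean(scores),
               sigmaHigh = sd(scores), weightLow = 1, multiplier = multiplier,
               threshold = Inf, converged = FALSE))
  }
  lo <- which.min(best$mu); hi <- 3L - lo
  wLow <- if (lo == 1L) best$w else 1 - best$w
  pooled <- sqrt(wLow * best$sg[lo]^2 + (1 - wLow) * best$sg[hi]^2)
  sep <- abs(best$mu[hi] - best$mu[lo]) >= 0.5 * pooled
  new("BimodalThreshold", className = className,
      muLow = best$mu[lo], sigmaLow = best$sg[lo],
      muHigh = best$mu[hi], sigmaHigh = best$sg[hi],
      weightLow = wLow, multiplier = multiplier,
      threshold = if (sep) best$mu[lo] + multiplier * best$sg[lo] else Inf,
      converged = sep)
}

#' Multi-type score doublet filter
#'
#' Flags nuclei whose type score exceeds the class threshold for two or more
#' classes.
#'
#' @param scores nuclei x classes score matrix from [computeTypeScores()].
#' @param thresholds list of [BimodalThreshold-class] objects (or a named
#'   numeric vector), one per score column.
#' @return Named logical vector.
#' @export
multitypeDoubletFilter <- function(scores, thresholds) {
  if (is.list(thresholds))
    thresholds <- vapply(thresholds, scoreThreshold, numeric(1))
  if (!all(colnames(scores) %in% names(thresholds)))
    stop("thresholds missing for class(es): ",
         paste(setdiff(colnames(scores), names(thresholds)), collapse = ", "),
         call. = FALSE)
  thr <- thresholds[colnames(scores)]
  nAbove <- rowSums(sweep(scores, 2, thr, ">"))
  setNames(nAbove >= 2, rownames(scores))
}

#' Regional contamination filter
#'
#' Flags nuclei whose summed raw counts across the regional marker genes
#' reach `minCount` (default 1: any expression).
#'
#' @param x cohort or count matrix.
#' @param markers regional marker gene ids (default [regionalMarkers()]).
#' @param minCount flagging threshold on the summed counts.
#' @return Named logical vector.
#' @export
regionalContaminationFilter <- function(x, markers = regionalMarkers(),
                                        minCount = 1) {
  counts <- .getCounts(x)
  if (!length(markers)) stop("marker list is empty", call. = FALSE)
  present <- intersect(markers, rownames(counts))
  if (!length(present))
    stop("none of the regional markers are present in the matrix",
         call. = FALSE)
  tot <- Matrix::colSums(counts[present, , drop = FALSE])
  setNames(tot >= minCount, colnames(counts))
}

#' Gene prevalence filter
#'
#' Keeps genes detected (count >= 1) in at least `minCells` nuclei.
#'
#' @param x cohort or count matrix.
#' @param minCells prevalence threshold (default 3).
#' @return Named logical keep-mask over genes.
#' @export
genePrevalenceFilter <- function(x, minCells = 3) {
  counts <- .getCounts(x)
  setNames(Matrix::rowSums(counts >= 1) >= minCells, rownames(counts))
}

#' Run the full nuclei QC cascade
#'
#' Applies the filtering stages in order — consensus doublets (when external
#' calls are supplied), hard thresholds, polynomial gene~UMI outliers,
#' multi-type marker-score doublets, regional contamination — each stage
#' seeing only the survivors of the previous one, then removes low-prevalence
#' genes. Returns the filtered cohort, the per-stage flag table and a funnel
#' report whose conservation (input = output + sum of removals) is enforced
#' by the report class's validity.
#'
#' @param sce cohort `SingleCellExperiment` with colData fields `n_umi`,
#'   `n_genes`, `mito_frac`.
#' @param panel marker panel for type scoring.
#' @param cfg a [qcConfig()].
#' @param doubletCalls optional nuclei x runs logical matrix of external
#'   caller runs; when `NULL` the consensus stage is skipped.
#' @param seed seed for the mixture fits.
#' @return List with `sce` (filtered), `report` ([QcReport-class]), `flags`
#'   (data.frame nucleus x stage; `NA` when a stage never saw the nucleus),
#'   and `thresholds` (the fitted [BimodalThreshold-class] objects).
#' @export
runQcCascade <- function(sce, panel, cfg = qcConfig(), doubletCalls = NULL,
                         seed = 1L) {
  meta <- as.data.frame(SummarizedExperiment::colData(sce))
  meta$nucleus_id <- colnames(sce)
  nInput <- ncol(sce)
  stageNames <- c("consensus_doublets", "hard_thresholds",
                  "polynomial_outliers", "multitype_score_doublets",
                  "regional_contamination")
  flags <- data.frame(matrix(NA, nInput, length(stageNames),
                             dimnames = list(meta$nucleus_id, stageNames)))
  alive <- rep(TRUE, nInput)
  names(alive) <- meta$nucleus_id
  stages <- data.frame(stage = character(), n_flagged_new = integer(),
                       n_remaining = integer(), stringsAsFactors = FALSE)
  record <- function(stage, flag) {
    flags[names(flag), stage] <<- unname(flag)
    alive[names(flag)[flag]] <<- FALSE
    stages <<- rbind(stages, data.frame(
      stage = stage, n_flagged_new = sum(flag), n_remaining = sum(alive),
      stringsAsFactors = FALSE))
  }

  if (!is.null(doubletCalls)) {
    if (is.null(rownames(doubletCalls)))
      rownames(doubletCalls) <- meta$nucleus_id
    f <- consensusDoubletFilter(doubletCalls[alive, , drop = FALSE],
                                cfg$consensusFrac)
    record("consensus_doublets", f)
  } else {
    stages <- rbind(stages, data.frame(stage = "consensus_doublets",
                                       n_flagged_new = 0L,
                                       n_remaining = sum(alive)))
  }

  record("hard_thresholds", basicThresholdFilter(meta[alive, ], cfg))
  record("polynomial_outliers", polynomialOutlierFilter(meta[alive, ], cfg))

  scores <- computeTypeScores(sce[, alive], panel, targetSum = cfg$targetSum)
  thresholds <- lapply(colnames(scores), function(cls)
    fitBimodalThreshold(scores[, cls], multiplier = cfg$gmmSdMultiplier,
                        className = cls, seed = seed))
  names(thresholds) <- colnames(scores)
  record("multitype_score_doublets", multitypeDoubletFilter(scores, thresholds))

  record("regional_contamination",
         regionalContaminationFilter(sce[, alive],
                                     minCount = cfg$minMarkerCountRegional))

  keptSce <- sce[, alive]
  geneKeep <- genePrevalenceFilter(keptSce, cfg$minCellsPerGene)
  keptSce <- keptSce[geneKeep, ]

  report <- new("QcReport", stages = stages, nInput = as.integer(nInput),
                nOutput = as.integer(sum(alive)),
                genesRemoved = as.integer(sum(!geneKeep)))
  validObject(report)
  list(sce = keptSce, report = report, flags = flags, thresholds = thresholds)
}
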