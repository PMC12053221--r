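#' Per-sample subpopulation composition table
#'
#' Counts and percentages of each subpopulation per sample; percentages are
#' relative to the sample's labeled nuclei (the analysis universe after QC),
#' and an aggregated per-condition-by-region layout is attached as attribute
#' `pooled` (percentages relative to each condition x region pool).
#'
#' @param meta data.frame with `sample_id`, `condition`, `region`, and a
#'   `label` column naming each nucleus's subpopulation.
#' @return data.frame with `sample_id`, `condition`, `region`,
#'   `subpopulation`, `n_cells`, `pct_of_sample`; attribute `pooled` holds
#'   the condition x region aggregation.
#' @export
compositionTable <- function(meta) {
  need <- c("sample_id", "condition", "region", "label")
  miss <- setdiff(need, names(meta))
  if (length(miss))
    stop("metadata missing: ", paste(miss, collapse = ", "), call. = FALSE)
  if (any(is.na(meta$label))) stop("every nucleus must be labeled", call. = FALSE)
  subpops <- sort(unique(meta$label))
  bySample <- unique(meta[c("sample_id", "condition", "region")])
  if (anyDuplicated(bySample$sample_id))
    stop("sample_id maps to multiple condition/region combinations",
         call. = FALSE)
  cnt <- table(meta$sample_id, factor(meta$label, levels = subpops))
  rows <- do.call(rbind, lapply(seq_len(nrow(bySample)), function(i) {
    sid <- bySample$sample_id[i]
    n <- cnt[sid, ]
    if (sum(n) == 0) stop(sprintf("sample '%s' has zero nuclei", sid),
                          call. = FALSE)
    data.frame(sample_id = sid, condition = bySample$condition[i],
               region = bySample$region[i], subpopulation = subpops,
               n_cells = as.integer(n),
               pct_of_sample = 100 * as.numeric(n) / sum(n),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  pooledTab <- table(paste(meta$condition, meta$region, sep = "."),
                     factor(meta$label, levels = subpops))
  pooled <- do.call(rbind, lapply(rownames(pooledTab), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    n <- pooledTab[k, ]
    data.frame(condition = parts[1], region = parts[2], subpopulation = subpops,
               n_cells = as.integer(n),
               pct_of_pool = 100 * as.numeric(n) / sum(n),
               stringsAsFactors = FALSE)
  }))
  rownames(pooled) <- NULL
  attr(rows, "pooled") <- pooled
  rows
}

#' Pooled percentage-point composition difference (PD minus Control)
#'
#' Computes, within one region, each subpopulation's pooled percentage under
#' PD minus its pooled percentage under Control. Deltas sum to zero across
#' subpopulations. The Bayesian compositional credibility call used on real
#' cohorts is not computed here; the returned table is in a layout directly
#' consumable by such a tool (credibility threshold 0.2 recorded as an
#' attribute for reference).
#'
#' @param composition table from [compositionTable()].
#' @param region region to compare within (`"CN"` or `"Pu"`).
#' @return data.frame with `subpopulation`, `pct_control`, `pct_pd`,
#'   `delta_pp` (percentage points).
#' @export
conditionDelta <- function(composition, region) {
  pooled <- attr(composition, "pooled")
  if (is.null(pooled)) stop("composition lacks the pooled layout", call. = FALSE)
  pooled <- pooled[pooled$region == region, ]
  for (cond in c("Control", "PD"))
    if (!cond %in% pooled$condition)
      stop(sprintf("condition '%s' missing in region %s", cond, region),
           call. = FALSE)
  ctl <- pooled[pooled$condition == "Control", ]
  pd <- pooled[pooled$condition == "PD", ]
  m <- merge(ctl[c("subpopulation", "pct_of_pool")],
             pd[c("subpopulation", "pct_of_pool")],
             by = "subpopulation", suffixes = c("_control", "_pd"))
  out <- data.frame(subpopulation = m$subpopulation,
                    pct_control = m$pct_of_pool_control,
                    pct_pd = m$pct_of_pool_pd,
                    delta_pp = m$pct_of_pool_pd - m$pct_of_pool_control,
                    stringsAsFactors = FALSE)
  attr(out, "credibilityThreshold") <- 0.2
  out
}

#' Stratify a composition analysis by a covariate
#'
#' Splits the nucleus metadata by the covariate and recomputes the
#' composition table per stratum, preserving its invariants.
#'
#' @param meta labeled nucleus metadata as for [compositionTable()], with the
#'   covariate column present.
#' @param covariate `"sex"` or `"region"`.
#' @return Named list of composition tables, one per stratum.
#' @export
stratifyBy <- function(meta, covariate = c("sex", "region")) {
  covariate <- match.arg(covariate)
  if (!covariate %in% names(meta))
    stop(sprintf("covariate '%s' not in metadata", covariate), call. = FALSE)
  lapply(split(meta, meta[[covariate]]), compositionTable)
}

# All permutations of 1..n as an n x n! matrix (used for exact Spearman p).
.allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .allPermutations(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 1L
  for (k in seq_len(n)) {
    idx <- c(seq_len(k - 1L), seq(k + 1L, length.out = n - k))
    for (j in seq_len(ncol(sub))) {
      out[, col] <- c(k, idx[sub[, j]])
      col <- col + 1L
    }
  }
  out
}

#' Spearman rank correlation with midranks and exact small-sample p
#'
#' Computes Spearman's rho on midranks (ties averaged). For `n` at most
#' `exactMax` the two-sided p-value is computed by exhaustive enumeration of
#' all n! orderings of one variable; otherwise by the t-distribution
#' approximation.
#'
#' @param x,y equal-length finite numeric vectors, n >= 3.
#' @param exactMax largest n for which the exhaustive p is used (default 7;
#'   may be raised to 9).
#' @return List with `rho`, `p_value`, `n_pairs`, `method`.
#' @export
spearmanTest <- function(x, y, exactMax = 7L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("rho undefined for a constant vector", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exactMax) {
    perms <- .allPermutations(n)
    rhoPerm <- as.numeric(cor(ry, matrix(rx[perms], nrow = n)))
    p <- mean(abs(rhoPerm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n_pairs = n, method = method)
}

#' Correlate a subpopulation ratio with per-sample intensities
#'
#' For each sample, the ratio is the numerator subpopulation's percentage
#' over the denominator's. Samples are retained only when they have strictly
#' more than `minCells` cells in the numerator population and in the
#' denominator population; the surviving (ratio, intensity) pairs go into a
#' Spearman rank correlation.
#'
#' @param composition table from [compositionTable()].
#' @param intensities named numeric vector of per-sample intensities (names
#'   are sample ids).
#' @param numeratorPop,denominatorPop subpopulation names.
#' @param minCells retention cutoff (default 5; strictly more than).
#' @return List as [spearmanTest()] plus `samples_used` and the per-sample
#'   `ratios`.
#' @export
ratioVsIntensity <- function(composition, intensities, numeratorPop,
                             denominatorPop, minCells = 5) {
  for (p in c(numeratorPop, denominatorPop))
    if (!p %in% composition$subpopulation)
      stop(sprintf("subpopulation '%s' absent from composition", p),
           call. = FALSE)
  num <- composition[composition$subpopulation == numeratorPop, ]
  den <- composition[composition$subpopulation == denominatorPop, ]
  m <- merge(num[c("sample_id", "n_cells", "pct_of_sample")],
             den[c("sample_id", "n_cells", "pct_of_sample")],
             by = "sample_id", suffixes = c("_num", "_den"))
  m <- m[m$sample_id %in% names(intensities), ]
  keep <- m$n_cells_num > minCells & m$n_cells_den > minCells
  m <- m[keep, ]
  if (nrow(m) < 3)
    stop(sprintf("fewer than 3 samples survive the >%d-cell filter", minCells),
         call. = FALSE)
  ratio <- m$pct_of_sample_num / m$pct_of_sample_den
  res <- spearmanTest(ratio, intensities[m$sample_id])
  res$samples_used <- m$sample_id
  res$ratios <- setNames(ratio, m$sample_id)
  res
}
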