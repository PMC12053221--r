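#' Spatial cell quality control
#'
#' Keeps cells with at least `minCounts` total counts and at least
#' `minGenes` detected genes.
#'
#' @param cells data.frame with a `cell_id` column.
#' @param expr genes x cells count matrix keyed by `cell_id`.
#' @param minCounts,minGenes retention thresholds (defaults 40 and 10;
#'   boundary values are kept).
#' @return The filtered `cells` data.frame, with attribute `kept` (logical).
#' @export
spatialQc <- function(cells, expr, minCounts = 40, minGenes = 10) {
  if (is.null(expr)) stop("no expression attached", call. = FALSE)
  if (!all(cells$cell_id %in% colnames(expr)))
    stop("expression missing for some cells", call. = FALSE)
  expr <- expr[, cells$cell_id, drop = FALSE]
  keep <- Matrix::colSums(expr) >= minCounts &
    Matrix::colSums(expr > 0) >= minGenes
  out <- cells[keep, , drop = FALSE]
  attr(out, "kept") <- setNames(as.logical(keep), cells$cell_id)
  out
}

#' Radius neighbor graph per sample
#'
#' Builds undirected edges between cells of the same sample within Euclidean
#' distance `radius` (inclusive). No self edges, no cross-sample edges.
#'
#' @param cells data.frame with `cell_id`, `x`, `y`, `sample_id`.
#' @param radius neighborhood radius in micrometres (default 124).
#' @return data.frame of edges with integer columns `i`, `j` (row indices
#'   into `cells`, i < j) and attribute `radius`.
#' @export
radiusGraph <- function(cells, radius = 124) {
  if (radius <= 0) stop("radius must be positive", call. = FALSE)
  edges <- list()
  for (sid in unique(cells$sample_id)) {
    idx <- which(cells$sample_id == sid)
    if (length(idx) < 2) next
    d <- as.matrix(dist(cells[idx, c("x", "y")]))
    hit <- which(upper.tri(d) & d <= radius, arr.ind = TRUE)
    if (nrow(hit))
      edges[[sid]] <- data.frame(i = idx[hit[, 1]], j = idx[hit[, 2]])
  }
  out <- if (length(edges)) do.call(rbind, edges)
         else data.frame(i = integer(), j = integer())
  rownames(out) <- NULL
  attr(out, "radius") <- radius
  out
}

# Count edges per unordered label pair given integer label codes.
.pairCounts <- function(ei, ej, code, L) {
  a <- pmin(code[ei], code[ej])
  b <- pmax(code[ei], code[ej])
  tabulate((a - 1L) * L + b, nbins = L * L)
}

#' Permutation z-score neighborhood enrichment between labels
#'
#' Counts observed adjacency per unordered label pair on the neighbor graph
#' and compares it to a null built by shuffling labels over cells (globally
#' by default, or within sample). z = (observed - null mean) / null sd;
#' pairs with zero null variance are flagged degenerate and reported as 0.
#'
#' @param edges edge table from [radiusGraph()].
#' @param labels label per cell (same order as the cells the edges index).
#' @param nPerm number of permutations (>= 10; default 1000).
#' @param seed RNG seed.
#' @param permuteWithinSample shuffle labels within sample instead of
#'   globally; requires `sample`.
#' @param sample per-cell sample ids (only needed for within-sample
#'   permutation).
#' @return A [NeighborhoodEnrichment-class] object.
#' @export
neighborhoodEnrichment <- function(edges, labels, nPerm = 1000L, seed = 1L,
                                   permuteWithinSample = FALSE,
                                   sample = NULL) {
  labels <- as.character(labels)
  n <- length(labels)
  if (n < 2) stop("need at least 2 cells", call. = FALSE)
  if (nPerm < 10) stop("nPerm must be at least 10", call. = FALSE)
  if (nrow(edges) && max(edges$i, edges$j) > n)
    stop("edge indices exceed the number of labeled cells", call. = FALSE)
  levs <- sort(unique(labels))
  L <- length(levs)
  code <- match(labels, levs)
  obs <- .pairCounts(edges$i, edges$j, code, L)
  set.seed(deriveSeed(seed, "nhood"))
  sums <- numeric(L * L); sq <- numeric(L * L)
  for (b in seq_len(nPerm)) {
    perm <- if (permuteWithinSample) {
      stopifnot(!is.null(sample))
      p <- integer(n)
      for (sid in unique(sample)) {
        ix <- which(sample == sid)
        p[ix] <- code[ix][sample.int(length(ix))]
      }
      p
    } else {
      code[sample.int(n)]
    }
    cnt <- .pairCounts(edges$i, edges$j, perm, L)
    sums <- sums + cnt
    sq <- sq + cnt^2
  }
  mu <- sums / nPerm
  sdv <- sqrt(pmax(sq / nPerm - mu^2, 0) * nPerm / (nPerm - 1))
  toMat <- function(v) {
    m <- matrix(0, L, L, dimnames = list(levs, levs))
    for (a in seq_len(L)) for (b in a:L) m[a, b] <- m[b, a] <- v[(a - 1L) * L + b]
    m
  }
  obsM <- toMat(obs); muM <- toMat(mu); sdM <- toMat(sdv)
  degen <- sdM == 0
  z <- ifelse(degen, 0, (obsM - muM) / ifelse(degen, 1, sdM))
  new("NeighborhoodEnrichment", z = z, observed = obsM, nullMean = muM,
      nullSd = sdM, degenerate = degen, nPerm = as.integer(nPerm),
      radius = attr(edges, "radius") %||% NA_real_)
}

#' Per-cell module score
#'
#' Library-size-normalized log expression is z-scored per gene across cells;
#' a cell's score is the mean z over the module genes. Zero-variance module
#' genes are skipped with a warning.
#'
#' @param expr genes x cells count matrix.
#' @param moduleGenes module gene ids (>= 1 present).
#' @param targetSum normalization target.
#' @return Named numeric score per cell.
#' @export
moduleScore <- function(expr, moduleGenes, targetSum = 1e4) {
  if (!length(moduleGenes)) stop("empty module", call. = FALSE)
  present <- intersect(moduleGenes, rownames(expr))
  if (!length(present))
    stop("no module genes present in the matrix", call. = FALSE)
  norm <- as.matrix(normalizeCounts(expr[present, , drop = FALSE],
                                    targetSum = targetSum))
  sds <- apply(norm, 1, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance module gene(s) skipped",
            call. = FALSE)
    norm <- norm[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
    if (!nrow(norm)) return(setNames(rep(0, ncol(expr)), colnames(expr)))
  }
  zs <- (norm - rowMeans(norm)) / sds
  setNames(colMeans(zs), colnames(expr))
}

#' Compare module scores between conditions
#'
#' Two-sided Wilcoxon rank-sum test of per-cell module scores between PD and
#' Control cells, with the direction of the difference reported.
#'
#' @param scores numeric per-cell scores.
#' @param condition per-cell condition (`"Control"`/`"PD"`).
#' @return List with `statistic`, `p_value`, `direction` (sign of PD minus
#'   Control median), `medians`.
#' @export
compareModuleScores <- function(scores, condition) {
  condition <- as.character(condition)
  for (cond in c("Control", "PD"))
    if (!any(condition == cond))
      stop(sprintf("condition '%s' is empty", cond), call. = FALSE)
  pd <- scores[condition == "PD"]
  ctl <- scores[condition == "Control"]
  wt <- wilcox.test(pd, ctl, exact = FALSE, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = sign(stats::median(pd) - stats::median(ctl)),
       medians = c(Control = stats::median(ctl), PD = stats::median(pd)))
}
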