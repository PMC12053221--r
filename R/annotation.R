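#' Assign lineage classes from marker-panel scores
#'
#' Each nucleus is labeled with the class of its highest type score; ties are
#' broken by panel order (reported via the `nTies` attribute) and nuclei
#' whose scores are all zero are labeled `"unassigned"`.
#'
#' @param x cohort or count matrix.
#' @param panel named list of marker gene ids per class.
#' @param targetSum normalization target for the scores.
#' @return Named character vector of labels with attribute `nTies`.
#' @export
assignClasses <- function(x, panel, targetSum = 1e4) {
  if (!length(panel)) stop("empty marker panel", call. = FALSE)
  scores <- computeTypeScores(x, panel, targetSum = targetSum)
  best <- max.col(scores, ties.method = "first")
  labels <- colnames(scores)[best]
  maxScore <- scores[cbind(seq_len(nrow(scores)), best)]
  labels[maxScore == 0] <- "unassigned"
  nTies <- sum(rowSums(scores == maxScore) > 1 & maxScore > 0)
  structure(setNames(labels, rownames(scores)), nTies = nTies)
}

# Vectorized one-vs-rest Wilcoxon rank-sum (normal approximation with tie
# and continuity correction), matching wilcox.test(correct = TRUE,
# exact = FALSE) per gene. Operating on a genes x cells matrix of normalized
# log expression; returns per-cluster z and two-sided p.
.rankSumOneVsRest <- function(expr, labels) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  ranks <- t(apply(expr, 1, rank))
  # tie correction term per gene: sum(t^3 - t) over tied groups
  tieTerm <- apply(expr, 1, function(v) {
    t <- rle(sort(v))$lengths; sum(t^3 - t)
  })
  out <- list()
  for (cl in sort(unique(labels))) {
    inCl <- labels == cl
    n1 <- sum(inCl); n2 <- n - n1
    R1 <- rowSums(ranks[, inCl, drop = FALSE])
    U <- R1 - n1 * (n1 + 1) / 2
    mu <- n1 * n2 / 2
    sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tieTerm / (n * (n - 1))))
    z <- ifelse(sigma > 0,
                (U - mu - sign(U - mu) * 0.5) / sigma, 0)
    p <- 2 * pnorm(-abs(z))
    out[[cl]] <- data.frame(cluster = cl, gene = rownames(expr),
                            rank_statistic = z, p_value = pmin(p, 1),
                            stringsAsFactors = FALSE)
  }
  out
}

#' One-vs-rest Wilcoxon marker ranking across clusters
#'
#' For every cluster, compares each gene's normalized log expression in the
#' cluster against all other nuclei with a two-sided Wilcoxon rank-sum test
#' (normal approximation with tie and continuity correction). Fold changes
#' are log2 ratios of mean normalized expression with a protective
#' pseudocount; Benjamini-Hochberg adjusted p-values are reported alongside
#' the raw ones. Genes are ordered by the rank statistic within cluster.
#'
#' @param x cohort or count matrix.
#' @param labels cluster label per nucleus (any source: marker-based
#'   annotation or an external community-detection run).
#' @param targetSum library-size normalization target.
#' @param pseudocount protects the fold-change ratio (default 1e-9).
#' @return data.frame with `cluster`, `gene`, `log2_fc`, `p_value`,
#'   `adjusted_p`, `rank_statistic`.
#' @export
rankMarkers <- function(x, labels, targetSum = 1e4, pseudocount = 1e-9) {
  counts <- .getCounts(x)
  labels <- as.character(labels)
  stopifnot(length(labels) == ncol(counts))
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least 2 clusters", call. = FALSE)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("cluster(s) with fewer than 2 nuclei: ",
         paste(small, collapse = ", "), call. = FALSE)
  normLinear <- normalizeCounts(counts, targetSum = targetSum, log = FALSE)
  normLog <- log1p(normLinear)
  res <- .rankSumOneVsRest(normLog, labels)
  out <- lapply(names(res), function(cl) {
    inCl <- labels == cl
    m1 <- Matrix::rowMeans(normLinear[, inCl, drop = FALSE])
    m0 <- Matrix::rowMeans(normLinear[, !inCl, drop = FALSE])
    df <- res[[cl]]
    df$log2_fc <- log2((m1 + pseudocount) / (m0 + pseudocount))
    df$adjusted_p <- p.adjust(df$p_value, method = "BH")
    df[order(-df$rank_statistic), ]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("cluster", "gene", "log2_fc", "p_value", "adjusted_p",
          "rank_statistic")]
}

#' Select cluster markers by fold-change and significance cutoffs
#'
#' Keeps genes with log2 fold change strictly above `minLfc` and raw p-value
#' strictly below `maxP`, ordered by rank statistic.
#'
#' @param de marker table from [rankMarkers()].
#' @param minLfc log2 fold-change cutoff (default 0.5, strict).
#' @param maxP p-value cutoff (default 0.05, strict).
#' @return Named list of per-cluster marker gene vectors (possibly empty,
#'   with a warning).
#' @export
selectMarkers <- function(de, minLfc = 0.5, maxP = 0.05) {
  keep <- de[de$log2_fc > minLfc & de$p_value < maxP, ]
  out <- split(keep$gene, factor(keep$cluster, levels = unique(de$cluster)))
  empty <- names(out)[lengths(out) == 0]
  if (length(empty) || !nrow(de))
    warning("no markers passed the cutoffs for: ",
            paste(if (nrow(de)) empty else "all clusters", collapse = ", "),
            call. = FALSE)
  out
}

#' Mean expression profiles per subpopulation
#'
#' @param x cohort or count matrix.
#' @param labels subpopulation label per nucleus.
#' @param targetSum library-size normalization target.
#' @return genes x subpopulations matrix of mean normalized log expression.
#' @export
subpopulationProfiles <- function(x, labels, targetSum = 1e4) {
  counts <- .getCounts(x)
  norm <- normalizeCounts(counts, targetSum = targetSum)
  labs <- sort(unique(as.character(labels)))
  prof <- vapply(labs, function(cl)
    Matrix::rowMeans(norm[, labels == cl, drop = FALSE]),
    numeric(nrow(counts)))
  prof
}

#' Subpopulation dendrogram from correlation distance
#'
#' Hierarchical clustering of subpopulation mean-expression profiles with
#' distance 1 - Pearson correlation and complete linkage. Leaf order is made
#' deterministic by processing profiles in lexicographic name order.
#'
#' @param profiles genes x subpopulations matrix; each column needs nonzero
#'   variance.
#' @return An `hclust` object.
#' @export
buildDendrogram <- function(profiles) {
  if (ncol(profiles) < 2) stop("need at least 2 profiles", call. = FALSE)
  v <- apply(profiles, 2, var)
  if (any(v == 0))
    stop("zero-variance profile(s): ",
         paste(colnames(profiles)[v == 0], collapse = ", "), call. = FALSE)
  profiles <- profiles[, order(colnames(profiles)), drop = FALSE]
  d <- as.dist(1 - cor(profiles))
  hclust(d, method = "complete")
}

#' Export a dendrogram as Newick text
#'
#' @param hc an `hclust` from [buildDendrogram()].
#' @param path optional file path; when `NULL` the Newick string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
dendrogramNewick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
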