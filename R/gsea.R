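# Enrichment score of one gene set on a ranked list, computed from the hit
# positions only: the weighted running sum (hit increments proportional to
# |score|^exponent, normalized to 1; uniform miss decrement 1/(N - k)) is
# piecewise linear, so its extrema occur just before or at hit positions.
.esFromPositions <- function(pos, absw, N) {
  pos <- sort(pos)
  k <- length(pos)
  w <- absw[pos]
  sw <- sum(w)
  w <- if (sw > 0) w / sw else rep(1 / k, k)
  miss <- 1 / (N - k)
  cw <- cumsum(w)
  drop <- (pos - seq_len(k)) * miss   # misses seen before hit i
  after <- cw - drop
  before <- c(0, cw[-k]) - drop
  esPos <- max(after)
  esNeg <- min(c(before, 0))
  if (esPos >= -esNeg) {
    i <- which.max(after)
    list(es = esPos, leadingIdx = pos[seq_len(i)])
  } else {
    i <- which.min(before)
    list(es = esNeg, leadingIdx = pos[i:k])
  }
}

#' Preranked gene set enrichment analysis with a permutation null
#'
#' Computes, for every gene set, the weighted Kolmogorov-Smirnov-like
#' running-sum enrichment score on the ranked list (hit increments
#' proportional to |score|^`weightExponent` normalized to one, uniform miss
#' decrements), a gene-label permutation null built by drawing `nPerm` random
#' sets of the same size, the normalized enrichment score (ES divided by the
#' mean |null ES| of matching sign), a one-sided nominal p on the matching
#' sign, and an FDR q-value by pooling sign-matched null and observed NES
#' values across sets. With `weightExponent = 0` the statistic reduces to the
#' classical unweighted Kolmogorov-Smirnov form.
#'
#' @param ranked data.frame with columns `gene`, `score`, or a named numeric
#'   vector of scores; sorted internally by decreasing score.
#' @param sets named list of gene-id vectors.
#' @param nPerm permutations per set (default 1000).
#' @param weightExponent hit-weight exponent (default 1).
#' @param seed RNG seed for the permutation null.
#' @return data.frame with `pathway`, `size`, `ES`, `NES`, `p`, `q`, and a
#'   `leadingEdge` list-column. Sets with empty intersection are skipped with
#'   a warning; a set covering the whole list is an error.
#' @export
prerankedGsea <- function(ranked, sets, nPerm = 1000L, weightExponent = 1,
                          seed = 1L) {
  if (is.data.frame(ranked)) {
    genes <- as.character(ranked$gene)
    scores <- as.numeric(ranked$score)
  } else {
    genes <- names(ranked)
    scores <- as.numeric(ranked)
  }
  if (anyDuplicated(genes)) stop("ranked list has duplicate genes", call. = FALSE)
  if (any(!is.finite(scores))) stop("ranking scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  genes <- genes[ord]; scores <- scores[ord]
  N <- length(genes)
  absw <- abs(scores)^weightExponent
  set.seed(deriveSeed(seed, "gsea_null"))

  res <- vector("list", length(sets))
  nullEs <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    nm <- names(sets)[i]
    pos <- which(genes %in% sets[[i]])
    k <- length(pos)
    if (k == 0L) {
      warning(sprintf("set '%s' has no genes in the ranked list; skipped", nm),
              call. = FALSE)
      next
    }
    if (k == N)
      stop(sprintf("set '%s' covers the whole ranked list", nm), call. = FALSE)
    obs <- .esFromPositions(pos, absw, N)
    null <- vapply(seq_len(nPerm), function(b)
      .esFromPositions(sample.int(N, k), absw, N)$es, numeric(1))
    posNull <- null[null >= 0]
    negNull <- null[null < 0]
    if (obs$es >= 0) {
      denom <- if (length(posNull)) mean(posNull) else mean(abs(null))
      nes <- if (denom > 0) obs$es / denom else 0
      p <- (1 + sum(posNull >= obs$es)) / (1 + length(posNull))
    } else {
      denom <- if (length(negNull)) mean(abs(negNull)) else mean(abs(null))
      nes <- if (denom > 0) obs$es / denom else 0
      p <- (1 + sum(negNull <= obs$es)) / (1 + length(negNull))
    }
    nullNes <- ifelse(null >= 0,
                      null / (if (length(posNull) && mean(posNull) > 0)
                                mean(posNull) else 1),
                      null / (if (length(negNull)) mean(abs(negNull)) else 1))
    nullEs[[i]] <- nullNes
    res[[i]] <- data.frame(pathway = nm, size = k, ES = obs$es, NES = nes,
                           p = p, stringsAsFactors = FALSE)
    res[[i]]$leadingEdge <- list(genes[obs$leadingIdx])
  }
  keep <- !vapply(res, is.null, logical(1))
  out <- do.call(rbind, res[keep])
  if (is.null(out) || !nrow(out)) return(out)
  pooled <- unlist(nullEs[keep])
  out$q <- vapply(out$NES, function(nes) {
    if (nes >= 0) {
      nullFrac <- sum(pooled >= nes) / max(sum(pooled >= 0), 1)
      obsFrac <- sum(out$NES >= nes) / max(sum(out$NES >= 0), 1)
    } else {
      nullFrac <- sum(pooled <= nes) / max(sum(pooled < 0), 1)
      obsFrac <- sum(out$NES <= nes) / max(sum(out$NES < 0), 1)
    }
    min(1, nullFrac / max(obsFrac, .Machine$double.eps))
  }, numeric(1))
  rownames(out) <- NULL
  out[, c("pathway", "size", "ES", "NES", "p", "q", "leadingEdge")]
}

#' Filter GSEA records by NES magnitude and FDR
#'
#' Keeps records with |NES| strictly above `minAbsNes` and q strictly below
#' `maxQ`.
#'
#' @param records GSEA result table with `NES` and `q` columns.
#' @param minAbsNes absolute NES cutoff (default 0.5).
#' @param maxQ FDR cutoff (default 0.05).
#' @return Filtered records.
#' @export
filterEnriched <- function(records, minAbsNes = 0.5, maxQ = 0.05) {
  records[abs(records$NES) > minAbsNes & records$q < maxQ, , drop = FALSE]
}

#' Merge redundant pathways across contrasts
#'
#' Collapses records keyed by (contrast, pathway) to one row per pathway with
#' mean NES, mean FDR over its contrast occurrences, and gene coverage: the
#' union of leading-edge genes across occurrences divided by the pathway's
#' gene-set size.
#'
#' @param records GSEA table with `contrast`, `pathway`, `NES`, `q` and a
#'   `leadingEdge` list-column.
#' @param sets the gene-set collection the pathways come from.
#' @return data.frame with `pathway`, `n_contrasts`, `mean_NES`, `mean_FDR`,
#'   `gene_coverage`, and list-columns `contrasts` and `leadingUnion`.
#' @export
mergeRedundant <- function(records, sets) {
  miss <- setdiff(unique(records$pathway), names(sets))
  if (length(miss))
    stop("pathway(s) absent from the collection: ",
         paste(head(miss, 3), collapse = ", "), call. = FALSE)
  out <- do.call(rbind, lapply(split(records, records$pathway), function(rr) {
    union_ <- sort(unique(unlist(rr$leadingEdge)))
    df <- data.frame(pathway = rr$pathway[1], n_contrasts = nrow(rr),
                     mean_NES = mean(rr$NES), mean_FDR = mean(rr$q),
                     gene_coverage = length(union_) /
                       length(sets[[rr$pathway[1]]]),
                     stringsAsFactors = FALSE)
    df$contrasts <- list(unique(rr$contrast))
    df$leadingUnion <- list(union_)
    df
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise Jaccard similarity of gene sets
#'
#' @param sets named list of non-empty gene-id vectors.
#' @return Symmetric matrix with unit diagonal.
#' @export
jaccardMatrix <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets", call. = FALSE)
  if (any(lengths(sets) == 0)) stop("empty gene set", call. = FALSE)
  n <- length(sets)
  J <- diag(1, n)
  dimnames(J) <- list(names(sets), names(sets))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    a <- sets[[i]]; b <- sets[[j]]
    J[i, j] <- J[j, i] <- length(intersect(a, b)) / length(union(a, b))
  }
  J
}

#' Cluster pathways into superpathways by Jaccard similarity
#'
#' Agglomerative clustering on distance 1 - Jaccard, cut into flat clusters
#' at the distance threshold. Cluster ids are renumbered in order of first
#' member appearance for determinism.
#'
#' @param jaccard symmetric similarity matrix from [jaccardMatrix()].
#' @param linkage agglomeration method (default `"average"`).
#' @param threshold distance cut height (default 0.8).
#' @return Named integer vector of cluster labels.
#' @export
clusterSuperpathways <- function(jaccard, linkage = "average",
                                 threshold = 0.8) {
  if (!isSymmetric(unname(jaccard)))
    stop("similarity matrix must be symmetric", call. = FALSE)
  hc <- hclust(as.dist(1 - jaccard), method = linkage)
  raw <- cutree(hc, h = threshold)
  ids <- unique(raw[rownames(jaccard)])
  setNames(match(raw, ids), names(raw))
}

#' Summarize superpathway clusters
#'
#' @param clusters named cluster labels from [clusterSuperpathways()].
#' @param merged merged pathway table from [mergeRedundant()].
#' @param sets gene-set collection (for union gene content).
#' @param corpus optional list of per-cluster member-name vectors used as the
#'   labeling corpus; defaults to the clusters themselves.
#' @return data.frame with `cluster`, `n_members`, `mean_NES`, `mean_FDR`,
#'   `gene_coverage`, `label`, and list-columns `members`, `genes`.
#' @export
summarizeSuperpathways <- function(clusters, merged, sets, corpus = NULL) {
  stopifnot(all(merged$pathway %in% names(clusters)))
  cl <- clusters[merged$pathway]
  groups <- split(merged, cl)
  if (is.null(corpus)) corpus <- lapply(groups, function(g) g$pathway)
  out <- do.call(rbind, lapply(names(groups), function(k) {
    g <- groups[[k]]
    lab <- labelSuperpathway(g$pathway, corpus = corpus)
    df <- data.frame(cluster = as.integer(k), n_members = nrow(g),
                     mean_NES = mean(g$mean_NES), mean_FDR = mean(g$mean_FDR),
                     gene_coverage = mean(g$gene_coverage),
                     label = paste(lab, collapse = "; "),
                     stringsAsFactors = FALSE)
    df$members <- list(sort(g$pathway))
    df$genes <- list(sort(unique(unlist(sets[g$pathway]))))
    df
  }))
  rownames(out) <- NULL
  out[order(out$cluster), ]
}

.labelStopwords <- c("of", "the", "and", "in", "to", "a", "an", "for",
                     "with", "by", "via", "on", "at", "from", "into",
                     "or", "as", "is", "go", "gobp", "gocc", "gomf",
                     "kegg", "reactome", "hallmark", "wp", "hsa")

.tokenizeName <- function(name) {
  toks <- strsplit(tolower(gsub("[^A-Za-z0-9]+", " ", name)), " +")[[1]]
  toks[nzchar(toks)]
}

#' Deterministic n-gram labels for a superpathway
#'
#' Tokenizes member pathway names (lowercase, separators split, stopwords
#' and pure numbers removed), enumerates contiguous 1-3-token phrases,
#' scores each by corpus-weighted frequency (term frequency across member
#' names, times an inverse-cluster-frequency weight when a corpus of other
#' clusters is supplied, times the phrase length in words), and returns the
#' top two distinct phrases; ties break lexicographically.
#'
#' @param memberNames pathway names of the cluster's members.
#' @param corpus optional list of member-name vectors for all clusters,
#'   used for the inverse-frequency weight.
#' @return Character vector of up to two phrases.
#' @export
labelSuperpathway <- function(memberNames, corpus = NULL) {
  if (!length(memberNames)) stop("empty cluster", call. = FALSE)
  phraseSet <- function(names_) {
    unique(unlist(lapply(names_, function(nm) {
      toks <- setdiff(.tokenizeName(nm), .labelStopwords)
      toks <- toks[!grepl("^[0-9]+$", toks)]
      if (!length(toks)) return(character())
      unlist(lapply(1:3, function(L) {
        if (length(toks) < L) return(character())
        vapply(seq_len(length(toks) - L + 1), function(s)
          paste(toks[s:(s + L - 1)], collapse = " "), character(1))
      }))
    })))
  }
  phraseCount <- function(names_) {
    tab <- table(unlist(lapply(unique(names_), function(nm) {
      toks <- setdiff(.tokenizeName(nm), .labelStopwords)
      toks <- toks[!grepl("^[0-9]+$", toks)]
      if (!length(toks)) return(character())
      unlist(lapply(1:3, function(L) {
        if (length(toks) < L) return(character())
        vapply(seq_len(length(toks) - L + 1), function(s)
          paste(toks[s:(s + L - 1)], collapse = " "), character(1))
      }))
    })))
    tab
  }
  tf <- phraseCount(memberNames)
  if (!length(tf)) {
    raw <- table(unlist(lapply(memberNames, .tokenizeName)))
    if (!length(raw)) stop("no tokens in member names", call. = FALSE)
    return(names(raw)[order(-raw, names(raw))][1])
  }
  idf <- rep(1, length(tf))
  names(idf) <- names(tf)
  if (!is.null(corpus) && length(corpus) > 1) {
    df <- vapply(names(tf), function(ph)
      sum(vapply(corpus, function(names_) ph %in% phraseSet(names_),
                 logical(1))), numeric(1))
    idf <- log(1 + length(corpus) / pmax(df, 1))
  }
  nWords <- vapply(strsplit(names(tf), " ", fixed = TRUE), length, integer(1))
  score <- as.numeric(tf) * idf[names(tf)] * nWords
  ord <- order(-score, names(tf))
  head(names(tf)[ord], 2)
}
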