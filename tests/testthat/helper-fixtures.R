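# Shared fixtures, generated once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# The study-scale cohort: 5,000 nuclei, planted 10% doublets / 5%
# contaminants / 2% gene~UMI outliers at the default separations.
sharedCohort <- function() {
  if (is.null(.fixtures$sce))
    .fixtures$sce <- generateCohort(synthConfig(seed = 7))
  .fixtures$sce
}

sharedQc <- function() {
  if (is.null(.fixtures$qc)) {
    sce <- sharedCohort()
    .fixtures$qc <- runQcCascade(sce, S4Vectors::metadata(sce)$panel,
                                 seed = 7)
  }
  .fixtures$qc
}

# A small cohort for fast structural tests.
smallSynthConfig <- function(seed = 2, ...) {
  synthConfig(
    seed = seed, nGenes = 600L,
    samples = data.frame(sample_id = c("A1", "A2", "B1", "B2"),
                         condition = c("Control", "Control", "PD", "PD"),
                         region = c("CN", "Pu", "CN", "Pu"),
                         sex = c("M", "F", "M", "F"),
                         n_nuclei = 80L, stringsAsFactors = FALSE),
    outlierGeneOffset = 300L, ...)
}

# Sensitivity/specificity of one cascade stage against a ground-truth flag,
# evaluated over the nuclei the stage actually saw.
stagePerformance <- function(flags, stage, truth) {
  seen <- !is.na(flags[[stage]])
  list(sens = mean(flags[seen & truth, stage]),
       spec = mean(!flags[seen & !truth, stage]),
       nTrue = sum(seen & truth))
}

# Exhaustive enrichment-score oracle: ES for every same-size gene subset.
allSubsetES <- function(scores, k, weightExponent = 1) {
  N <- length(scores)
  ord <- order(scores, decreasing = TRUE)
  sorted <- scores[ord]
  absw <- abs(sorted)^weightExponent
  apply(combn(N, k), 2, function(pos) {
    w <- absw[pos] / sum(absw[pos])
    miss <- 1 / (N - k)
    cw <- cumsum(w[order(pos)])
    pos <- sort(pos)
    drop <- (pos - seq_len(k)) * miss
    after <- cw - drop
    before <- c(0, cw[-k]) - drop
    esPos <- max(after); esNeg <- min(c(before, 0))
    if (esPos >= -esNeg) esPos else esNeg
  })
}

# Brute-force agglomerative clustering oracle (O(n^3)): merge heights for
# complete or average linkage on a distance matrix.
bruteAgglomerate <- function(d, method = c("complete", "average")) {
  method <- match.arg(method)
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      vals <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- if (method == "complete") max(vals) else mean(vals)
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

# Flat clusters from single-pass brute-force agglomeration stopped at a cut.
bruteFlatClusters <- function(d, method = "average", cutHeight = 0.8) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1) break
    best <- c(Inf, 0, 0)
    for (i in seq_len(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      vals <- d[clusters[[i]], clusters[[j]], drop = FALSE]
      h <- if (method == "complete") max(vals) else mean(vals)
      if (h < best[1]) best <- c(h, i, j)
    }
    if (best[1] > cutHeight) break
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  out <- integer(n)
  for (k in seq_along(clusters)) out[clusters[[k]]] <- k
  out
}

# Exhaustive neighborhood-enrichment oracle over all label arrangements of a
# small graph: exact null mean/sd of per-pair adjacency counts.
exhaustiveNhoodZ <- function(edges, labels) {
  n <- length(labels)
  levs <- sort(unique(labels))
  L <- length(levs)
  code <- match(labels, levs)
  count <- function(cd) {
    a <- pmin(cd[edges$i], cd[edges$j]); b <- pmax(cd[edges$i], cd[edges$j])
    tabulate((a - 1L) * L + b, nbins = L * L)
  }
  perms <- striatoglia:::.allPermutations(n)
  cnts <- apply(perms, 2, function(p) count(code[p]))
  mu <- rowMeans(cnts)
  sdv <- apply(cnts, 1, sd)
  obs <- count(code)
  toMat <- function(v) {
    m <- matrix(0, L, L, dimnames = list(levs, levs))
    for (a in seq_len(L)) for (b in a:L) m[a, b] <- m[b, a] <- v[(a - 1L) * L + b]
    m
  }
  list(z = toMat(ifelse(sdv > 0, (obs - mu) / ifelse(sdv > 0, sdv, 1), 0)),
       mean = toMat(mu), sd = toMat(sdv), obs = toMat(obs))
}
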