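#' @importFrom methods new validObject is slot
#' @importFrom stats rnorm rpois rnbinom rbinom runif rbeta rlnorm sd var
#'   cor quantile dnorm pnorm pt setNames as.dist hclust cutree cophenetic
#'   p.adjust t.test wilcox.test complete.cases coef lm
#' @importFrom utils head read.delim write.table combn
NULL

# Stable 31-ary string hash modulo 2^31 - 1; used to derive per-sample and
# per-stage RNG sub-seeds so that adding a sample or toggling a stage does
# not perturb the streams of the others.
stableHash <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 31 + c) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed from a base seed and a string tag
#'
#' @param seed integer base seed.
#' @param tag character scalar naming the stream (sample id, stage name).
#' @return An integer in [0, 2^31 - 2] usable with [set.seed()].
#' @export
deriveSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) %% 2147483647 + stableHash(tag)) %% 2147483647)
}

#' Library-size normalize and log-transform a count matrix
#'
#' Columns (nuclei) are scaled to a common target sum, then log1p-transformed.
#' Zero-depth columns are left at zero.
#'
#' @param counts gene x nucleus matrix (dense or `Matrix` sparse).
#' @param targetSum per-nucleus total after scaling (default 1e4).
#' @param log apply log1p after scaling (default TRUE).
#' @return Matrix of the same shape and sparsity as the input.
#' @export
normalizeCounts <- function(counts, targetSum = 1e4, log = TRUE) {
  depth <- Matrix::colSums(counts)
  scale <- ifelse(depth > 0, targetSum / depth, 0)
  out <- counts %*% Matrix::Diagonal(x = scale)
  dimnames(out) <- dimnames(counts)
  if (log) out <- log1p(out)
  out
}

# counts accessor tolerant of plain matrices and SingleCellExperiment
.getCounts <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    x
  }
}

.assertScalarNumeric <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("'%s' must be a finite scalar in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
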