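#' QcReport: the nuclei quality-control funnel
#'
#' Records, stage by stage, how many nuclei each filter newly flagged and how
#' many survived, plus the number of genes removed by the prevalence filter.
#' Validity enforces funnel conservation: input = output + sum of removals.
#'
#' @slot stages data.frame with columns `stage`, `n_flagged_new`, `n_remaining`.
#' @slot nInput,nOutput integer nucleus counts before/after the cascade.
#' @slot genesRemoved integer count of genes dropped by the prevalence filter.
#'
#' @export
setClass("QcReport",
  representation(stages = "data.frame", nInput = "integer",
                 nOutput = "integer", genesRemoved = "integer"),
  prototype(stages = data.frame(stage = character(), n_flagged_new = integer(),
                                n_remaining = integer()),
            nInput = 0L, nOutput = 0L, genesRemoved = 0L))

setValidity("QcReport", function(object) {
  st <- object@stages
  msg <- character()
  need <- c("stage", "n_flagged_new", "n_remaining")
  if (!all(need %in% names(st)))
    return(paste("stages must have columns", paste(need, collapse = ", ")))
  if (nrow(st)) {
    if (any(diff(st$n_remaining) > 0))
      msg <- c(msg, "n_remaining must be non-increasing along stages")
    if (object@nInput - sum(st$n_flagged_new) != object@nOutput)
      msg <- c(msg, "funnel conservation violated: input - flagged != output")
    if (utils::tail(st$n_remaining, 1) != object@nOutput)
      msg <- c(msg, "last n_remaining must equal nOutput")
  } else if (object@nInput != object@nOutput) {
    msg <- c(msg, "no stages but input != output")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn QcReport stage table accessor
#' @param object,x a `QcReport`
#' @export
setGeneric("qcStages", function(object) standardGeneric("qcStages"))

#' @rdname QcReport
#' @export
setMethod("qcStages", "QcReport", function(object) object@stages)

#' @rdname QcReport
#' @export
setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport: %d nuclei in, %d out (%d genes removed by prevalence filter)\n",
              object@nInput, object@nOutput, object@genesRemoved))
  if (nrow(object@stages)) print(object@stages, row.names = FALSE)
})

#' BimodalThreshold: two-component Gaussian mixture score threshold
#'
#' Result of fitting a univariate two-component Gaussian mixture to a
#' cell-type score distribution. The exclusion threshold is the mean of the
#' lower component plus `multiplier` of its standard deviations. When the two
#' components are indistinguishable the fit is flagged non-converged and the
#' threshold is +Inf, so the downstream filter flags nothing.
#'
#' @slot className character; which panel class the scores belong to.
#' @slot muLow,sigmaLow,muHigh,sigmaHigh numeric mixture parameters.
#' @slot weightLow numeric mixing proportion of the lower component.
#' @slot multiplier numeric; number of lower-component SDs above its mean.
#' @slot threshold numeric; `muLow + multiplier * sigmaLow`, or +Inf.
#' @slot converged logical.
#'
#' @export
setClass("BimodalThreshold",
  representation(className = "character", muLow = "numeric",
                 sigmaLow = "numeric", muHigh = "numeric",
                 sigmaHigh = "numeric", weightLow = "numeric",
                 multiplier = "numeric", threshold = "numeric",
                 converged = "logical"))

setValidity("BimodalThreshold", function(object) {
  msg <- character()
  if (object@converged) {
    if (object@muLow > object@muHigh)
      msg <- c(msg, "muLow must not exceed muHigh")
    if (object@sigmaLow <= 0 || object@sigmaHigh <= 0)
      msg <- c(msg, "sigmas must be positive")
    if (!is.finite(object@threshold))
      msg <- c(msg, "threshold must be finite when converged")
  }
  if (object@weightLow < 0 || object@weightLow > 1)
    msg <- c(msg, "weightLow must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn BimodalThreshold numeric threshold accessor
#' @param object a `BimodalThreshold`
#' @export
setGeneric("scoreThreshold", function(object) standardGeneric("scoreThreshold"))

#' @rdname BimodalThreshold
#' @export
setMethod("scoreThreshold", "BimodalThreshold", function(object) object@threshold)

#' @rdname BimodalThreshold
#' @export
setMethod("show", "BimodalThreshold", function(object) {
  cat(sprintf(
    "BimodalThreshold[%s]: low N(%.3g, %.3g) w=%.2f, high N(%.3g, %.3g); threshold=%.4g%s\n",
    object@className, object@muLow, object@sigmaLow, object@weightLow,
    object@muHigh, object@sigmaHigh, object@threshold,
    if (object@converged) "" else " (not converged)"))
})

#' NeighborhoodEnrichment: label-pair spatial adjacency z-scores
#'
#' Observed same/cross-label adjacency counts on a radius neighbor graph,
#' compared to a label-permutation null. z = (observed - null mean)/null sd;
#' pairs whose null sd is zero are flagged degenerate and reported as z = 0.
#'
#' @slot z,observed,nullMean,nullSd symmetric label x label matrices.
#' @slot degenerate logical matrix flagging zero-variance null pairs.
#' @slot nPerm integer number of permutations.
#' @slot radius numeric neighborhood radius in micrometres.
#'
#' @export
setClass("NeighborhoodEnrichment",
  representation(z = "matrix", observed = "matrix", nullMean = "matrix",
                 nullSd = "matrix", degenerate = "matrix", nPerm = "integer",
                 radius = "numeric"))

setValidity("NeighborhoodEnrichment", function(object) {
  msg <- character()
  if (!isSymmetric(unname(object@z))) msg <- c(msg, "z must be symmetric")
  if (any(!is.finite(object@z))) msg <- c(msg, "z must be finite (degenerate pairs are 0)")
  if (length(msg)) msg else TRUE
})

#' @describeIn NeighborhoodEnrichment z-score matrix accessor
#' @param object a `NeighborhoodEnrichment`
#' @export
setGeneric("enrichmentZ", function(object) standardGeneric("enrichmentZ"))

#' @rdname NeighborhoodEnrichment
#' @export
setMethod("enrichmentZ", "NeighborhoodEnrichment", function(object) object@z)

#' @rdname NeighborhoodEnrichment
#' @export
setMethod("show", "NeighborhoodEnrichment", function(object) {
  cat(sprintf("NeighborhoodEnrichment: %d labels, radius %g um, %d permutations\n",
              nrow(object@z), object@radius, object@nPerm))
  print(round(object@z, 2))
})
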