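#' Summarize ROI measurements per donor
#'
#' Pools ROI rows within donor x region x marker: mean DAB intensity is
#' averaged over ROIs, and percent positive area is 100 times the summed
#' positive area over the summed total area.
#'
#' @param roi ROI table in the layout of [tableSchema]`("roiTable")`.
#' @return data.frame with `donor_id`, `region`, `condition`, `marker`,
#'   `mean_intensity` (NA when not measured), `pct_positive` (NA when no
#'   area rows).
#' @export
summarizeDonor <- function(roi) {
  key <- interaction(roi$donor_id, roi$region, roi$marker, drop = TRUE)
  out <- do.call(rbind, lapply(split(roi, key), function(rr) {
    ints <- rr$value[rr$measurement_type == "mean_dab_intensity"]
    posA <- sum(rr$value[rr$measurement_type == "positive_area_um2"])
    totA <- sum(rr$value[rr$measurement_type == "total_area_um2"])
    hasArea <- any(rr$measurement_type == "positive_area_um2")
    if (hasArea && totA == 0)
      stop(sprintf("donor '%s' has zero total area", rr$donor_id[1]),
           call. = FALSE)
    if (hasArea && !any(rr$measurement_type == "total_area_um2"))
      stop(sprintf("donor '%s' has positive area but no total area",
                   rr$donor_id[1]), call. = FALSE)
    data.frame(donor_id = rr$donor_id[1], region = rr$region[1],
               condition = rr$condition[1], marker = rr$marker[1],
               mean_intensity = if (length(ints)) mean(ints) else NA_real_,
               pct_positive = if (hasArea) 100 * posA / totA else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Two-sample t test on per-donor values
#'
#' Welch (unequal-variance) t by default; pooled-variance variant by flag.
#'
#' @param group1,group2 numeric vectors, each of length >= 2.
#' @param welch use the Welch-Satterthwaite form (default TRUE).
#' @return List with `t`, `p`, `df`, `means`, `sems`, `n`.
#' @export
twoSampleT <- function(group1, group2, welch = TRUE) {
  if (length(group1) < 2 || length(group2) < 2)
    stop("each group needs at least 2 values", call. = FALSE)
  tt <- t.test(group1, group2, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       means = c(mean(group1), mean(group2)),
       sems = c(sd(group1) / sqrt(length(group1)),
                sd(group2) / sqrt(length(group2))),
       n = c(length(group1), length(group2)))
}

#' Reconstruct a t statistic from group means and SEMs
#'
#' t = (mean1 - mean2) / sqrt(sem1^2 + sem2^2); useful for checking reported
#' group comparisons against their published summary statistics.
#'
#' @param mean1,sem1,mean2,sem2 group summaries; SEMs must be positive.
#' @return The t statistic.
#' @export
tFromSummary <- function(mean1, sem1, mean2, sem2) {
  if (sem1 <= 0 || sem2 <= 0) stop("SEMs must be positive", call. = FALSE)
  (mean1 - mean2) / sqrt(sem1^2 + sem2^2)
}

#' Spearman correlations between donor-level feature pairs
#'
#' For each requested pair of columns in a donor summary table, computes the
#' Spearman correlation (delegating to [spearmanTest()]) per region slice.
#'
#' @param summaries donor summary table (e.g. from [summarizeDonor()],
#'   possibly reshaped so features are columns).
#' @param pairs list of character 2-vectors of column names.
#' @param by optional column to slice by (e.g. `"region"`).
#' @return data.frame with `feature_x`, `feature_y`, slice, `rho`, `p_value`,
#'   `n_pairs`.
#' @export
featureCorrelations <- function(summaries, pairs, by = NULL) {
  slices <- if (is.null(by)) list(all = summaries)
            else split(summaries, summaries[[by]])
  out <- do.call(rbind, lapply(names(slices), function(sl) {
    df <- slices[[sl]]
    do.call(rbind, lapply(pairs, function(pr) {
      x <- df[[pr[1]]]; y <- df[[pr[2]]]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 3)
        stop(sprintf("fewer than 3 donors for %s vs %s in slice '%s'",
                     pr[1], pr[2], sl), call. = FALSE)
      r <- spearmanTest(x[ok], y[ok])
      data.frame(feature_x = pr[1], feature_y = pr[2], slice = sl,
                 rho = r$rho, p_value = r$p_value, n_pairs = r$n_pairs,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}
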