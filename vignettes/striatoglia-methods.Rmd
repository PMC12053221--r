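---
title: "Methods: QC, enrichment, and spatial statistics in striatoglia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QC, enrichment, and spatial statistics in striatoglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`striatoglia` implements the statistical procedures of an
oligodendroglia-focused single-nucleus and spatial transcriptomics analysis
of the parkinsonian dorsal striatum. This vignette documents the models,
the tunable parameters and their defaults, the numerical choices, and what
the synthetic-cohort generator does and does not emulate.

## The nuclei QC cascade

Quality control is a *sequential funnel*: each stage sees only the
survivors of the previous one, and the `QcReport` class enforces
conservation (input = output + sum of per-stage removals) as a validity
invariant. The order — consensus doublets, hard thresholds, polynomial
gene~UMI outliers, marker-score doublets, regional contamination, then the
gene prevalence filter — follows the order in which such filters are
applied in practice: cheap per-nucleus summaries first, model-based filters
on the cleaned remainder.

**Consensus doublets.** External doublet callers are stochastic, so the
input is a nuclei × runs logical matrix; a nucleus is flagged when called
in strictly more than `consensusFrac` (default 0.10) of runs. The caller
itself is out of scope: any tool's per-run calls can be supplied.

**Hard thresholds.** Defaults: fewer than 500 UMIs or 1,200 genes, more
than 250,000 UMIs or 15,000 genes, or mitochondrial fraction above 0.10.
All bounds are strict, so boundary values (exactly 500 UMIs, exactly 10%
mitochondrial content) are retained.

**Polynomial gene~UMI outliers.** Detected genes track UMIs along a smooth
saturating curve; we fit detected genes against UMIs as a degree-2
polynomial in log10–log10 space (least squares on the surviving nuclei)
and flag deviations larger than `residThresholdGenes = 2000`. The residual
scale was a genuinely open choice: a deviation of 2,000 is only meaningful
in *gene counts*, not in log units (log10 gene counts span roughly 3–4.2
here), so the fitted value is back-transformed and the residual measured
on the linear detected-gene scale. `residOnLogScale = TRUE` switches to
the literal log-scale difference for sensitivity analyses.

**Marker-score doublets.** Per-class cell-type scores are the mean, over
the class's marker genes, of library-size-normalized (target sum
`targetSum = 1e4`), log1p-transformed expression. The normalization is not
dictated by the score definition; the 10k-target log1p convention of the
single-cell ecosystem is used so scores are comparable across depths.
Across a mixed population each class's score distribution is bimodal
(expressing vs non-expressing nuclei), modeled as a univariate
two-component Gaussian mixture fit by EM:

* initialization at the 25th/75th percentiles, shared starting SD of half
  the sample SD, equal weights;
* 5 restarts (the first from the quantile init, the rest jittered), keeping
  the best log-likelihood; tolerance 1e-6; at most 500 iterations; the RNG
  stream is derived from the seed and the class name, so fits are
  reproducible and independent of evaluation order;
* degenerate guard: if the two component means are closer than half the
  pooled (weight-averaged) SD, or a component collapses, the fit is marked
  non-converged and the threshold set to +Inf, so the stage flags nothing
  rather than fabricating a cut in a unimodal distribution.

The exclusion threshold is μ_low + 4·σ_low, the lower component's mean
plus four of its standard deviations (`gmmSdMultiplier = 4`). Nuclei above
threshold for **two or more** classes are removed as doublets; exceeding a
single class's threshold is expected for genuine members of that class.

**Regional contamination.** Nuclei expressing the neighboring-region
markers *NEUROD2*, *TMEM155*, *CARTPT*, *SLC17A7* are removed. The default
cutoff is a summed raw count of 1 — the literal reading of "expressing" —
but `minMarkerCountRegional` is exposed because ambient counts can make a
single molecule an aggressive criterion.

**Gene prevalence.** After nucleus filtering, genes detected in fewer than
`minCellsPerGene = 3` nuclei are dropped.

## Lineage annotation and marker ranking

Class assignment is the argmax of the marker-panel scores; ties break by
panel order (and are counted), and all-zero nuclei are `"unassigned"`.
Cluster labels for marker ranking can come from any source — the
marker-based annotation here, or an external community-detection run;
graph clustering itself (PCA/harmony/Louvain) is deliberately out of scope.

Marker ranking is a one-vs-rest two-sided Wilcoxon rank-sum per gene, in a
vectorized implementation of the normal approximation with tie and
continuity correction (it matches `wilcox.test(exact = FALSE, correct =
TRUE)` to 1e-10 in the tests; vectorization is what makes genome-wide by
cluster ranking tractable). Fold changes are log2 ratios of mean
normalized (linear-scale) expression with a 1e-9 pseudocount; log2 was
chosen and is labeled in outputs since the base is conventional but not
universal. Selection uses the raw p-value with strict cutoffs
(log2 FC > 0.5, p < 0.05), and Benjamini–Hochberg adjusted p-values are
reported alongside for transparency.

Subpopulation dendrograms use distance 1 − Pearson r between mean
normalized log-expression profiles over all retained genes (the gene space
is deliberately not restricted) with complete linkage; profiles are
processed in lexicographic name order so ties resolve deterministically.

## Composition and correlation statistics

Per-sample percentages are relative to the sample's labeled nuclei — the
analysis universe after QC — and a pooled condition × region layout is
attached for condition deltas (PD − Control percentage points, which sum
to zero by construction). The Bayesian compositional model used on real
cohorts is pluggable, not reimplemented: the count layout it needs is
emitted, and its credibility threshold (0.2) is recorded as metadata only.

The ratio-vs-intensity procedure divides one subpopulation's per-sample
percentage by another's, keeps samples with strictly more than five cells
in *both* populations (the filter is applied per population
independently), and computes a Spearman correlation. Spearman uses
midranks for ties; the p-value is an exhaustive permutation enumeration
for n ≤ 7 (exposed up to 9) and the t-approximation above that.

## Preranked GSEA and superpathways

The enrichment score is the classic weighted running sum: walking down the
ranked list, hits increment by |score|^α normalized to sum 1 (α =
`weightExponent`, default 1; α = 0 recovers the unweighted
Kolmogorov–Smirnov statistic) and misses decrement uniformly by 1/(N −
N_hits); ES is the extremum. Because the statistic is piecewise linear,
ES is computed from hit positions alone in O(k log k).

The null is a *gene-label* permutation: `nPerm` random same-size gene sets
(default 1,000). Sample-level permutation is unavailable for preranked
lists, and the ranking metric fed in is deliberately unconstrained — any
score column works. NES divides ES by the mean |null ES| of matching sign;
the nominal p is one-sided on the matching sign with add-one smoothing;
the FDR q pools sign-matched null and observed NES across sets (null tail
fraction over observed tail fraction, clipped at 1).

Enriched records (|NES| > 0.5 and q < 0.05, strict) are merged across
contrasts — mean NES, mean FDR, and gene coverage, defined here (it has no
standard definition) as the union of leading-edge genes across contrast
occurrences divided by the set size. Merged pathways are clustered on
distance 1 − Jaccard with average linkage, cut at distance 0.8. Whether
the 0.8 threshold applies to similarity or distance was open; distance was
chosen (near-duplicate sets with J ≥ 0.8 then co-cluster, disjoint sets
stay apart) and the threshold is a parameter.

Superpathway labels come from a deterministic TF-IDF n-gram scorer rather
than a language-model keyword extractor: member names are lowercased and
tokenized, stopwords and database prefixes removed, contiguous 1–3-token
phrases scored by frequency × inverse-cluster-frequency × phrase length,
and the top two distinct phrases returned with lexicographic tie-breaks.
This keeps the "top two ranked 1–3-word phrases" contract reproducible
with no model dependency.

## Spatial neighborhood enrichment

Spatial QC keeps cells with at least 40 counts and 10 detected genes.
Radius graphs connect cells of the same sample within 124 µm (inclusive —
conventional ball-query semantics); there are no self or cross-sample
edges. Neighborhood enrichment counts edges per unordered label pair and
standardizes against `nPerm` label shuffles (default global shuffling,
mirroring a concatenated-samples analysis; within-sample permutation is
offered because cross-sample composition differences can inflate z).
Pairs with zero null variance are flagged degenerate and reported as z = 0.

A note on calibration: for a correctly calibrated permutation z, a single
shuffled-label replicate yields per-pair z-scores distributed
approximately N(0,1), so the mean of |z| over pairs concentrates near
E|N(0,1)| ≈ 0.80 — it does not shrink toward zero. The calibration tests
therefore check *unbiasedness*: per-pair z averaged over independent
shuffle replicates must be near zero.

Module scores are the mean across module genes of per-gene z-scored
normalized log expression (zero-variance genes are skipped with a
warning); module *discovery* is out of scope — gene lists are inputs.
Condition comparisons use the two-sided rank-sum test.

## Histology statistics

ROIs are pooled within donor before testing — the donor is the statistical
unit — with percent positive area as 100 × Σ positive / Σ total area,
which is invariant to splitting ROIs. The default t test is Welch
(unequal variances; group sizes and spreads differ in practice), with the
pooled-variance form behind a flag. `tFromSummary` reconstructs
t = (m₁ − m₂)/√(SEM₁² + SEM₂²) from published group summaries; agreement
with raw-data t statistics is limited by SEM rounding, which is why the
acceptance checks allow ±0.05.

## The synthetic cohort generator

The generator's defaults define the study conditions used throughout the
tests: ten donors (five Control, five PD) split across CN and Pu, 500
nuclei each (5,000 total), 6,000 genes, six striatal classes
(oligodendrocytes, OPCs, astrocytes, microglia, neurons, vascular) with 25
markers each at fold-change 8, lognormal depth (log-mean log 5000, log-SD
0.3), negative-binomial counts (variance = μ + μ²/dispersion, dispersion
2), 10% doublets, 5% regional contaminants, 2% gene~UMI outliers, and a 2%
tail of mitochondrial fractions above 0.10. A modest PD composition shift
(oligodendrocytes 40→36%, neurons 12→16%) is planted so condition deltas
have a recoverable sign.

Mechanics chosen to mirror the physical failure modes: doublets are the
*sum of two full draws* from distinct classes (two nuclei in one droplet),
not averages; contaminants receive Poisson counts in the regional marker
genes; outliers receive `outlierGeneOffset = 5000` extra single-count
genes, breaking the gene~UMI curve by construction while barely moving
depth. Determinism is strict: one seeded stream per sample, derived by
stable string hashing of the sample id, so adding a sample never perturbs
the others; the same applies to pipeline stages.

The ROI generator plants intensity = intercept + slope × ratio +
condition offset + noise. With composition spread driven only by
multinomial sampling across ten donors, the between-sample ratio SD is a
few hundredths, so the defaults (slope −0.4, noise SD 0.005 on an
intercept of 0.30) are set so the planted negative association is clearly
recoverable by a rank correlation — matching the moderate negative
correlations such cohorts show — rather than drowned by measurement noise.

What the generator does *not* emulate: gene–gene correlation beyond class
structure, batch effects, ambient-RNA soup beyond the regional markers,
realistic spatial tissue architecture beyond rectangular bands, or
donor-level biological variability in expression profiles. Passing tests
demonstrate that the statistical machinery recovers planted structure at
realistic separations; they do not certify performance on real tissue,
where marker bleed, batch structure, and continuous cell states blur the
planted separations.

## Problem sizes and runtime choices

The default test and acceptance runs use the 5,000-nucleus cohort for the
QC funnel, n = 20,000 scores for mixture-threshold recovery, 1,000-gene
ranked lists with 1,000 permutations for GSEA (400 permutations across 200
sets for the null-uniformity check), 6–8-gene lists for exhaustive
enrichment enumeration, ≤ 8-node graphs for exhaustive neighborhood
enumeration, and two full pipeline runs for the byte-identity determinism
check. These sizes keep planted effects well inside detection limits while
the whole suite runs in minutes on one CPU.

## Known limitations

* The QC stages interact: an anomaly removed by an early stage is never
  seen by the stage that targets it (e.g., consensus doublet calls, when
  supplied, remove most doublets before the marker-score stage). Stage
  performance is therefore evaluated on the nuclei each stage actually saw.
* The gene-label permutation null for GSEA ignores inter-gene correlation,
  as all preranked GSEA implementations do; q-values on strongly correlated
  sets are approximate.
* The EM mixture fit assumes exactly two Gaussian components; heavy-tailed
  or three-modal score distributions will shift the threshold. The
  non-convergence guard only catches the unimodal case.
* Percent-positive and intensity summaries assume consistent units within
  a marker; no cross-marker normalization is attempted.
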