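#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' GeneSignature: an ordered set of signature gene identifiers
#'
#' A signature is an ordered, duplicate-free list of gene (or probe set)
#' identifiers, e.g. the 35 interferon-related genes used to characterise
#' type I IFN pathway activation in whole blood. Identifiers are treated as
#' opaque labels; they only need to match the row names of the expression
#' matrix they are used with.
#'
#' @slot name single character, a human-readable label for the signature.
#' @slot geneIds character vector of at least two unique, non-empty IDs.
#'
#' @examples
#' sig <- GeneSignature("demo", c("MX1", "OAS1", "IFIT1"))
#' geneIds(sig)
#' @export
setClass("GeneSignature",
  representation(name = "character", geneIds = "character"))

setValidity("GeneSignature", function(object) {
  msg <- NULL
  if (length(object@name) != 1L || is.na(object@name))
    msg <- c(msg, "'name' must be a single non-NA string")
  ids <- object@geneIds
  if (length(ids) < 2L)
    msg <- c(msg, "a signature needs at least 2 gene IDs")
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicated gene IDs in signature")
  if (any(is.na(ids) | !nzchar(ids)))
    msg <- c(msg, "gene IDs must be non-empty and non-NA")
  if (is.null(msg)) TRUE else msg
})

#' @rdname GeneSignature-class
#' @param name signature label.
#' @param geneIds character vector of unique gene IDs (length >= 2).
#' @export
GeneSignature <- function(name, geneIds) {
  new("GeneSignature", name = as.character(name),
      geneIds = as.character(geneIds))
}

#' SampleGroup: a labelled subset of samples
#'
#' Plumbing type used to carry the sample membership of the signature-high
#' and signature-low groups between the bootstrap clustering, prototype
#' construction and correlation profiling steps.
#'
#' @slot label group label (e.g. "high" or "low").
#' @slot sampleIds character vector of unique sample IDs (non-empty).
#' @export
setClass("SampleGroup",
  representation(label = "character", sampleIds = "character"))

setValidity("SampleGroup", function(object) {
  msg <- NULL
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(object@sampleIds) < 1L)
    msg <- c(msg, "a sample group cannot be empty")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicated sample IDs in group")
  if (is.null(msg)) TRUE else msg
})

#' @rdname SampleGroup-class
#' @param label group label.
#' @param sampleIds character vector of sample IDs.
#' @export
SampleGroup <- function(label, sampleIds) {
  new("SampleGroup", label = as.character(label),
      sampleIds = as.character(sampleIds))
}

#' PrototypePair: median reference profiles of the high and low groups
#'
#' Holds the two prototype vectors of the classifier: for each signature
#' gene, the median log2 expression in the signature-high and in the
#' signature-low training group. A sample is later classified by comparing
#' the Pearson correlation of its signature profile with each prototype.
#'
#' A constant prototype is rejected at construction: Pearson correlation
#' against a constant vector is undefined, so such a prototype can never
#' classify anything.
#'
#' @slot signature the [GeneSignature-class] the prototypes are indexed by.
#' @slot high numeric vector, per-gene medians of the high group (log2).
#' @slot low numeric vector, per-gene medians of the low group (log2).
#' @slot provenance list describing the training groups (labels, sizes).
#' @export
setClass("PrototypePair",
  representation(signature = "GeneSignature", high = "numeric",
                 low = "numeric", provenance = "list"))

setValidity("PrototypePair", function(object) {
  msg <- NULL
  m <- length(object@signature@geneIds)
  if (length(object@high) != m || length(object@low) != m)
    msg <- c(msg, "prototype vectors must have one entry per signature gene")
  if (!all(is.finite(object@high)) || !all(is.finite(object@low)))
    msg <- c(msg, "prototype values must be finite")
  if (length(unique(object@high)) < 2L)
    msg <- c(msg, "'high' prototype is constant; Pearson correlation undefined")
  if (length(unique(object@low)) < 2L)
    msg <- c(msg, "'low' prototype is constant; Pearson correlation undefined")
  if (is.null(msg)) TRUE else msg
})

#' CorrelationProfile: within-group co-expression structure of a signature
#'
#' For one group of samples: the full pairwise Pearson correlation matrix of
#' the signature genes (computed across the group's samples), a per-gene
#' correlation index (the median of that gene's correlations with the
#' remaining signature genes) and the group-level R_median (the median of
#' the correlation indexes), which summarises the group's global
#' co-activation level.
#'
#' @slot groupLabel label of the profiled sample group.
#' @slot geneIds signature gene IDs (order of rows/columns of `pairwise`).
#' @slot pairwise symmetric M x M Pearson correlation matrix, unit diagonal.
#' @slot index numeric vector of M per-gene correlation indexes.
#' @slot rMedian median of the correlation indexes.
#' @slot pairwiseMedian median of the M(M-1)/2 off-diagonal correlations
#'   (reported alongside `rMedian`; the two summaries are usually close).
#' @slot nSamples number of samples the correlations were computed over.
#' @export
setClass("CorrelationProfile",
  representation(groupLabel = "character", geneIds = "character",
                 pairwise = "matrix", index = "numeric",
                 rMedian = "numeric", pairwiseMedian = "numeric",
                 nSamples = "integer"))

setValidity("CorrelationProfile", function(object) {
  msg <- NULL
  m <- length(object@geneIds)
  pw <- object@pairwise
  if (!all(dim(pw) == c(m, m)))
    msg <- c(msg, "'pairwise' must be M x M")
  else {
    if (max(abs(pw - t(pw))) > 1e-8)
      msg <- c(msg, "'pairwise' must be symmetric")
    if (max(abs(diag(pw) - 1)) > 1e-8)
      msg <- c(msg, "'pairwise' must have unit diagonal")
    if (any(pw < -1 - 1e-8 | pw > 1 + 1e-8))
      msg <- c(msg, "correlations must lie in [-1, 1]")
    idx <- vapply(seq_len(m), function(j) stats::median(pw[j, -j]), 0)
    if (length(object@index) != m || max(abs(idx - object@index)) > 1e-8)
      msg <- c(msg, "'index' must be the per-gene median of off-diagonal correlations")
    if (abs(stats::median(object@index) - object@rMedian) > 1e-8)
      msg <- c(msg, "'rMedian' must be the median of the correlation indexes")
  }
  if (is.null(msg)) TRUE else msg
})

#' FilterReport: accounting of the two-stage expression filter
#'
#' Records what the intensity (median expression) and variability (MAD)
#' filters removed, in the order they were applied.
#'
#' @slot nInput number of genes before filtering.
#' @slot nAfterIntensity number retained after the intensity stage.
#' @slot nAfterMad number retained after the MAD stage.
#' @slot intensityThreshold log2 threshold of the intensity stage.
#' @slot madCutoff the median-of-MADs cutoff used by the MAD stage.
#' @slot removedIntensity IDs removed by the intensity stage.
#' @slot removedMad IDs removed by the MAD stage.
#' @export
setClass("FilterReport",
  representation(nInput = "integer", nAfterIntensity = "integer",
                 nAfterMad = "integer", intensityThreshold = "numeric",
                 madCutoff = "numeric", removedIntensity = "character",
                 removedMad = "character"))

setValidity("FilterReport", function(object) {
  msg <- NULL
  if (!(object@nInput >= object@nAfterIntensity &&
        object@nAfterIntensity >= object@nAfterMad))
    msg <- c(msg, "gene counts must be non-increasing across filter stages")
  if (length(object@removedIntensity) != object@nInput - object@nAfterIntensity)
    msg <- c(msg, "removedIntensity length inconsistent with counts")
  if (length(object@removedMad) != object@nAfterIntensity - object@nAfterMad)
    msg <- c(msg, "removedMad length inconsistent with counts")
  if (is.null(msg)) TRUE else msg
})

#' ScoreComparison: CABS call versus the classical mean-expression score
#'
#' Head-to-head comparison of the correlation-based call with the classical
#' signature score (per-sample mean expression of the signature genes
#' thresholded at the healthy-control mean + 1.96 SD): per-sample records,
#' the Spearman correlation between the decision variable and the mean
#' score, and the fraction of samples on which the two calls disagree.
#'
#' @slot records a [S4Vectors::DataFrame] with columns sample_id,
#'   mean_score, d, call_meanscore, call_cabs, discordant.
#' @slot threshold the mean-score threshold used (log2 units).
#' @slot agreementFraction fraction of concordant calls.
#' @slot discordanceFraction fraction of discordant calls.
#' @slot spearmanRho Spearman correlation between d and mean score.
#' @slot spearmanP two-sided p-value of the Spearman test.
#' @slot table 2 x 2 agreement table (CABS call x mean-score call).
#' @export
setClass("ScoreComparison",
  representation(records = "DataFrame", threshold = "numeric",
                 agreementFraction = "numeric",
                 discordanceFraction = "numeric",
                 spearmanRho = "numeric", spearmanP = "numeric",
                 table = "table"))

setValidity("ScoreComparison", function(object) {
  msg <- NULL
  if (abs(object@agreementFraction + object@discordanceFraction - 1) > 1e-8)
    msg <- c(msg, "agreement and discordance fractions must sum to 1")
  if (is.null(msg)) TRUE else msg
})

#' PairedMonitoringResult: before/after change of the decision variable
#'
#' Result of the paired longitudinal analysis within one baseline stratum:
#' the paired decision-variable values, the Wilcoxon signed-rank statistic
#' and two-sided p-value for the within-patient change, and the direction of
#' that change (sign of the median paired difference).
#'
#' @slot stratumLabel label of the baseline stratum ("high", "low", "all").
#' @slot pairs data.frame with columns patient_id, d_before, d_after.
#' @slot n number of pairs.
#' @slot wStatistic signed-rank statistic W (sum of positive-difference
#'   ranks); NA when every difference is zero.
#' @slot pValue two-sided p-value.
#' @slot direction "increase", "decrease" or "none".
#' @export
setClass("PairedMonitoringResult",
  representation(stratumLabel = "character", pairs = "data.frame",
                 n = "integer", wStatistic = "numeric", pValue = "numeric",
                 direction = "character"))

setValidity("PairedMonitoringResult", function(object) {
  msg <- NULL
  if (object@n != nrow(object@pairs))
    msg <- c(msg, "'n' must equal the number of pairs")
  if (!object@direction %in% c("increase", "decrease", "none"))
    msg <- c(msg, "direction must be increase/decrease/none")
  if (object@n > 0L) {
    md <- stats::median(object@pairs$d_after - object@pairs$d_before)
    want <- if (md > 0) "increase" else if (md < 0) "decrease" else "none"
    if (object@direction != want)
      msg <- c(msg, "direction inconsistent with median paired difference")
  }
  if (!is.na(object@pValue) && (object@pValue <= 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' CohortDesign: parameters of the synthetic cohort generator
#'
#' Describes a synthetic cohort as one or more sample groups sharing a
#' signature of `mSignature` genes plus `nBackground` uncorrelated
#' background genes. Within a group the signature genes follow a one-factor
#' model whose loading is chosen so the pairwise inter-gene Pearson
#' correlation equals `rho` exactly in the population; the group's mean
#' activation shift is applied through per-gene response weights. See the
#' methods vignette for the full model and the rationale for each default.
#'
#' @slot mSignature number of signature genes (default 35).
#' @slot nBackground number of background genes.
#' @slot groups data.frame with columns label, nSamples, rho, meanShift.
#' @slot baselineMean signature-average baseline expression (log2, default 8).
#' @slot noiseSd per-gene residual SD (log2, default 1).
#' @slot loadingJitter SD of per-gene loading heterogeneity (default 0.1).
#' @slot geneBaselineSd SD of per-gene baseline offsets (default 1.5).
#' @slot responseSpread half-width of the uniform per-gene activation
#'   response weights around 1 (default 1, i.e. weights in [0, 2]).
#' @slot seed optional integer seed stored with the design.
#' @slot geneSeed optional integer seed for the gene-level parameters
#'   (baseline offsets, response weights, loading jitter). Gene parameters
#'   are properties of the genes, not of a cohort: designs sharing a
#'   geneSeed generate cohorts over the same "biology", so prototypes fit
#'   on one cohort are applicable to the others. NA (default) draws them
#'   from the cohort seed's stream.
#' @export
setClass("CohortDesign",
  representation(mSignature = "integer", nBackground = "integer",
                 groups = "data.frame", baselineMean = "numeric",
                 noiseSd = "numeric", loadingJitter = "numeric",
                 geneBaselineSd = "numeric", responseSpread = "numeric",
                 seed = "integer", geneSeed = "integer"))

setValidity("CohortDesign", function(object) {
  msg <- NULL
  g <- object@groups
  need <- c("label", "nSamples", "rho", "meanShift")
  if (!all(need %in% names(g)))
    msg <- c(msg, paste("groups must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(g$rho < 0 | g$rho >= 1))
      msg <- c(msg, "group rho targets must lie in [0, 1)")
    if (any(g$nSamples < 1))
      msg <- c(msg, "group sizes must be >= 1")
    if (anyDuplicated(g$label))
      msg <- c(msg, "group labels must be unique")
    if (!all(is.finite(g$meanShift)))
      msg <- c(msg, "mean shifts must be finite")
  }
  if (object@mSignature < 2L)
    msg <- c(msg, "need at least 2 signature genes")
  if (object@noiseSd <= 0)
    msg <- c(msg, "noiseSd must be positive")
  if (object@loadingJitter < 0 || object@geneBaselineSd < 0 ||
      object@responseSpread < 0)
    msg <- c(msg, "spread parameters must be non-negative")
  if (!all(is.finite(c(object@baselineMean, object@noiseSd))))
    msg <- c(msg, "design parameters must be finite")
  if (is.null(msg)) TRUE else msg
})
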