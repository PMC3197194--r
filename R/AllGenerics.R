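#' @name cabsig-accessors
#' @title Accessors for cabsig classes
#' @description Small accessor generics for the package's S4 classes.
#' @param x an object.
#' @return The slot value named by the accessor.
NULL

#' @rdname cabsig-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname cabsig-accessors
#' @export
setGeneric("signatureName", function(x) standardGeneric("signatureName"))

#' @rdname cabsig-accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname cabsig-accessors
#' @export
setGeneric("groupLabel", function(x) standardGeneric("groupLabel"))

#' @rdname cabsig-accessors
#' @export
setGeneric("prototypeHigh", function(x) standardGeneric("prototypeHigh"))

#' @rdname cabsig-accessors
#' @export
setGeneric("prototypeLow", function(x) standardGeneric("prototypeLow"))

#' @rdname cabsig-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname cabsig-accessors
#' @export
setGeneric("rMedian", function(x) standardGeneric("rMedian"))

#' @rdname cabsig-accessors
#' @export
setGeneric("correlationIndex", function(x) standardGeneric("correlationIndex"))

#' @rdname cabsig-accessors
#' @export
setGeneric("pairwiseCorrelations",
           function(x) standardGeneric("pairwiseCorrelations"))

setMethod("geneIds", "GeneSignature", function(x) x@geneIds)
setMethod("geneIds", "PrototypePair", function(x) x@signature@geneIds)
setMethod("geneIds", "CorrelationProfile", function(x) x@geneIds)
setMethod("signatureName", "GeneSignature", function(x) x@name)
setMethod("sampleIds", "SampleGroup", function(x) x@sampleIds)
setMethod("groupLabel", "SampleGroup", function(x) x@label)
setMethod("groupLabel", "CorrelationProfile", function(x) x@groupLabel)
setMethod("prototypeHigh", "PrototypePair",
          function(x) stats::setNames(x@high, x@signature@geneIds))
setMethod("prototypeLow", "PrototypePair",
          function(x) stats::setNames(x@low, x@signature@geneIds))
setMethod("provenance", "PrototypePair", function(x) x@provenance)
setMethod("rMedian", "CorrelationProfile", function(x) x@rMedian)
setMethod("correlationIndex", "CorrelationProfile",
          function(x) stats::setNames(x@index, x@geneIds))
setMethod("pairwiseCorrelations", "CorrelationProfile", function(x) x@pairwise)

setMethod("show", "GeneSignature", function(object) {
  cat("GeneSignature '", object@name, "' with ",
      length(object@geneIds), " genes\n", sep = "")
  ids <- object@geneIds
  if (length(ids) > 6) ids <- c(ids[1:6], "...")
  cat("  ", paste(ids, collapse = ", "), "\n", sep = "")
})

setMethod("show", "SampleGroup", function(object) {
  cat("SampleGroup '", object@label, "': ", length(object@sampleIds),
      " samples\n", sep = "")
})

setMethod("show", "PrototypePair", function(object) {
  cat("PrototypePair over signature '", object@signature@name, "' (M = ",
      length(object@signature@geneIds), ")\n", sep = "")
  pr <- object@provenance
  if (length(pr))
    cat("  trained on:",
        paste(vapply(names(pr), function(nm)
          sprintf("%s (n = %s)", nm, pr[[nm]]$n %||% "?"), ""),
          collapse = ", "), "\n")
})

setMethod("show", "CorrelationProfile", function(object) {
  cat("CorrelationProfile '", object@groupLabel, "': M = ",
      length(object@geneIds), " genes, n = ", object@nSamples,
      " samples\n", sep = "")
  cat(sprintf("  R_median = %.3f (median of pairwise correlations %.3f)\n",
              object@rMedian, object@pairwiseMedian))
})

setMethod("show", "FilterReport", function(object) {
  cat("FilterReport\n")
  cat(sprintf("  input genes:           %d\n", object@nInput))
  cat(sprintf("  after intensity (>= %g): %d (removed %d)\n",
              object@intensityThreshold, object@nAfterIntensity,
              length(object@removedIntensity)))
  cat(sprintf("  after MAD (>= %.4g):    %d (removed %d)\n",
              object@madCutoff, object@nAfterMad,
              length(object@removedMad)))
})

setMethod("show", "ScoreComparison", function(object) {
  cat("ScoreComparison over", nrow(object@records), "samples\n")
  cat(sprintf("  mean-score threshold: %.4g\n", object@threshold))
  cat(sprintf("  Spearman rho = %.3f (p = %.3g)\n",
              object@spearmanRho, object@spearmanP))
  cat(sprintf("  discordant calls: %.1f%%\n",
              100 * object@discordanceFraction))
})

setMethod("show", "PairedMonitoringResult", function(object) {
  cat("PairedMonitoringResult stratum '", object@stratumLabel, "': ",
      object@n, " pairs\n", sep = "")
  cat(sprintf("  W = %s, two-sided p = %.4g, direction: %s\n",
              format(object@wStatistic), object@pValue, object@direction))
})

setMethod("show", "CohortDesign", function(object) {
  cat("CohortDesign:", object@mSignature, "signature genes +",
      object@nBackground, "background genes\n")
  for (i in seq_len(nrow(object@groups))) {
    g <- object@groups[i, ]
    cat(sprintf("  group '%s': n = %d, rho = %.2f, shift = %+.2f log2\n",
                g$label, g$nSamples, g$rho, g$meanShift))
  }
})
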