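#' Intensity filter: drop genes with low median expression
#'
#' Keeps exactly the genes whose median log2 expression across all samples
#' is at or above `threshold`; genes strictly below are eliminated. The
#' default of 6 log2 units corresponds to roughly twice a typical
#' microarray background level, but the threshold is scanner-dependent and
#' therefore exposed as a parameter. The sample axis is untouched.
#'
#' @param x matrix or SummarizedExperiment (genes x samples, log2 values).
#' @param threshold log2 intensity threshold (default 6).
#' @return list with `matrix` (the filtered object, same class as `x`) and
#'   `removed` (IDs of eliminated genes).
#' @export
intensityFilter <- function(x, threshold = 6) {
  m <- .exprs(x)
  if (nrow(m) == 0L) stop("empty expression matrix")
  med <- apply(m, 1L, stats::median)
  keep <- med >= threshold
  if (!any(keep))
    stop("intensity filter removed every gene (threshold ", threshold, ")")
  list(matrix = subsetExpression(x, genes = rownames(m)[keep]),
       removed = rownames(m)[!keep])
}

#' MAD filter: drop genes with low variability
#'
#' Computes each gene's median absolute deviation across samples (raw MAD,
#' `median(|x - median(x)|)`, without the 1.4826 consistency constant — the
#' cutoff is the median of the MADs themselves, so a constant would cancel)
#' and eliminates genes whose MAD is strictly lower than the median of all
#' per-gene MADs. Equality survives, so at least half the genes are always
#' retained.
#'
#' @param x matrix or SummarizedExperiment, normally the output of
#'   [intensityFilter()].
#' @return list with `matrix`, `removed` and `madCutoff` (the median of the
#'   per-gene MADs).
#' @export
madFilter <- function(x) {
  m <- .exprs(x)
  if (nrow(m) < 2L) stop("MAD filter needs at least 2 genes")
  mads <- apply(m, 1L, .rawMad)
  cutoff <- stats::median(mads)
  keep <- mads >= cutoff
  list(matrix = subsetExpression(x, genes = rownames(m)[keep]),
       removed = rownames(m)[!keep],
       madCutoff = cutoff)
}

#' Two-stage expression filtering (intensity, then MAD)
#'
#' Applies [intensityFilter()] followed by [madFilter()], the order in which
#' the two stages are defined: the MAD cutoff is the median of the MADs of
#' the genes that survive the intensity stage, so swapping the stages
#' changes the result. Returns the filtered matrix together with a
#' [FilterReport-class] accounting for both stages.
#'
#' @param x matrix or SummarizedExperiment.
#' @param threshold log2 intensity threshold (default 6).
#' @return list with `matrix` and `report`.
#' @examples
#' m <- matrix(rnorm(60, 8), 6, 10,
#'             dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
#' res <- runFilters(m)
#' res$report
#' @export
runFilters <- function(x, threshold = 6) {
  n0 <- nrow(.exprs(x))
  st1 <- intensityFilter(x, threshold)
  st2 <- madFilter(st1$matrix)
  report <- new("FilterReport",
    nInput = as.integer(n0),
    nAfterIntensity = as.integer(n0 - length(st1$removed)),
    nAfterMad = as.integer(nrow(.exprs(st2$matrix))),
    intensityThreshold = as.numeric(threshold),
    madCutoff = st2$madCutoff,
    removedIntensity = st1$removed,
    removedMad = st2$removed)
  list(matrix = st2$matrix, report = report)
}
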