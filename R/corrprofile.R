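#' Within-group correlation profile of a signature
#'
#' Computes, across the samples of one group, the pairwise Pearson
#' correlation matrix of the signature genes; from it, each gene's
#' correlation index (the median of its correlations with the remaining
#' signature genes) and the group-level R_median (the median of the
#' correlation indexes). A high R_median indicates that the signature genes
#' move together in that group — the co-activation the classifier exploits.
#' The median of the off-diagonal pairwise correlations is reported
#' alongside as `pairwiseMedian`.
#'
#' Correlations on two samples are degenerately +/-1, so groups of fewer
#' than 3 samples trigger a warning; a zero-variance gene within the group
#' is an error naming the gene.
#'
#' @param x matrix or SummarizedExperiment.
#' @param signature a [GeneSignature-class].
#' @param samples [SampleGroup-class], character vector of sample IDs, or
#'   NULL for all samples.
#' @param label group label for the profile (defaults to the SampleGroup's
#'   label, or "all").
#' @return a [CorrelationProfile-class].
#' @export
correlationProfile <- function(x, signature, samples = NULL, label = NULL) {
  stopifnot(is(signature, "GeneSignature"))
  if (is.null(label))
    label <- if (is(samples, "SampleGroup")) samples@label else "all"
  m <- .exprs(subsetExpression(x, genes = signature, samples = samples))
  n <- ncol(m)
  if (n < 2L) stop("degenerate group: need at least 2 samples")
  if (n == 2L)
    warning("correlation over 2 samples is degenerate (every value is +/-1)")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s) within group '", label, "': ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  pw <- stats::cor(t(m))
  pw <- (pw + t(pw)) / 2
  diag(pw) <- 1
  idx <- vapply(seq_len(nrow(pw)), function(j) stats::median(pw[j, -j]), 0)
  new("CorrelationProfile",
      groupLabel = label, geneIds = signature@geneIds,
      pairwise = pw, index = idx,
      rMedian = stats::median(idx),
      pairwiseMedian = stats::median(pw[upper.tri(pw)]),
      nSamples = as.integer(n))
}

#' Compare the correlation levels of two groups
#'
#' Two-sided Mann-Whitney U (rank-sum) test comparing the correlation
#' values of two [CorrelationProfile-class]s over the same signature. The
#' default unit is the M(M-1)/2 off-diagonal pairwise correlations; the
#' per-gene correlation indexes are available as an alternative unit.
#'
#' Correlations within a group share samples and are therefore not
#' independent observations; the p-value is descriptive, and flagged as
#' such in the returned `note`.
#'
#' @param a,b [CorrelationProfile-class] objects over the same signature.
#' @param unit "pairwise" (default) or "index".
#' @return list with `statistic` (the U statistic for `a`), `p.value`,
#'   `unit` and `note`.
#' @export
compareCorrelationLevels <- function(a, b, unit = c("pairwise", "index")) {
  unit <- match.arg(unit)
  stopifnot(is(a, "CorrelationProfile"), is(b, "CorrelationProfile"))
  if (!identical(a@geneIds, b@geneIds))
    stop("profiles are over different signatures")
  pick <- function(p) switch(unit,
    pairwise = p@pairwise[upper.tri(p@pairwise)],
    index = p@index)
  va <- pick(a)
  vb <- pick(b)
  wt <- suppressWarnings(stats::wilcox.test(va, vb, alternative = "two.sided"))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, unit = unit,
       note = paste("correlation values within a group share samples;",
                    "the p-value is descriptive"))
}
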