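#' Bootstrap the signature-high / signature-low groups by clustering
#'
#' Agglomerative hierarchical clustering of samples on their signature-gene
#' profiles, cut into two clusters. The cluster with the larger mean
#' signature expression is labelled "high", the other "low". The default
#' distance is 1 - Pearson correlation between sample profiles, matching
#' the correlation-centric framing of the classifier; the default linkage
#' is Ward, which is robust to the outlier-chaining that can make an
#' average-linkage two-cluster cut degenerate into a singleton split (see
#' the methods vignette). Ties in cluster labelling are broken by input
#' order, so the operation is deterministic.
#'
#' @param x matrix or SummarizedExperiment.
#' @param signature a [GeneSignature-class].
#' @param k number of clusters (the classifier is two-group; k must be 2).
#' @param linkage hclust agglomeration method (default "ward.D2";
#'   "average" and "complete" are the common alternatives).
#' @param distance "correlation" (1 - Pearson, default) or "euclidean".
#' @return named list of two [SampleGroup-class] objects, `high` and `low`.
#' @export
bootstrapGroups <- function(x, signature, k = 2,
                            linkage = "ward.D2",
                            distance = c("correlation", "euclidean")) {
  distance <- match.arg(distance)
  stopifnot(is(signature, "GeneSignature"))
  if (k != 2) stop("the classifier is two-group; k must be 2")
  m <- .exprs(subsetExpression(x, genes = signature))
  if (ncol(m) < 2L) stop("need at least 2 samples to cluster")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance signature profile for sample(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  d <- if (distance == "correlation") {
    cc <- stats::cor(m)
    if (anyNA(cc)) stop("undefined correlations between sample profiles")
    if (max(1 - cc[upper.tri(cc)]) < 1e-12)
      stop("degenerate clustering: all sample profiles are identical")
    stats::as.dist(1 - cc)
  } else {
    dd <- stats::dist(t(m))
    if (max(dd) < 1e-12)
      stop("degenerate clustering: all sample profiles are identical")
    dd
  }
  cl <- stats::cutree(stats::hclust(d, method = linkage), k = 2L)
  meanBy <- tapply(colMeans(m), cl, mean)
  hi <- as.integer(names(meanBy)[which.max(meanBy)])
  groups <- list(
    high = SampleGroup("high", colnames(m)[cl == hi]),
    low = SampleGroup("low", colnames(m)[cl != hi]))
  sizes <- vapply(groups, function(g) length(g@sampleIds), 0L)
  if (any(sizes < 2L))
    warning("cluster of size ", min(sizes),
            ": its prototype is a single sample's profile")
  groups
}

#' Build the prototype pair from labelled groups
#'
#' For each signature gene, the prototype entry of a group is the median of
#' that gene's expression over the group's samples (so a single outlying
#' sample cannot distort the prototype). Entries follow signature order.
#'
#' @param x matrix or SummarizedExperiment.
#' @param signature a [GeneSignature-class].
#' @param groups named list with elements `high` and `low`, each a
#'   [SampleGroup-class] or character vector of sample IDs; the groups must
#'   be disjoint and non-empty.
#' @return a [PrototypePair-class].
#' @export
buildPrototypes <- function(x, signature, groups) {
  stopifnot(is(signature, "GeneSignature"))
  if (!all(c("high", "low") %in% names(groups)))
    stop("'groups' must have elements named 'high' and 'low'")
  hiIds <- .sampleIdsOf(groups$high)
  loIds <- .sampleIdsOf(groups$low)
  if (length(hiIds) == 0L || length(loIds) == 0L)
    stop("both groups must be non-empty")
  if (length(intersect(hiIds, loIds)))
    stop("groups overlap: ",
         paste(intersect(hiIds, loIds), collapse = ", "))
  m <- .exprs(subsetExpression(x, genes = signature))
  .checkPresent(c(hiIds, loIds), colnames(m), "sample ID")
  med <- function(ids) apply(m[, ids, drop = FALSE], 1L, stats::median)
  high <- med(hiIds)
  low <- med(loIds)
  if (length(unique(high)) < 2L || length(unique(low)) < 2L)
    stop("invalid prototype: constant median profile")
  new("PrototypePair", signature = signature,
      high = unname(high), low = unname(low),
      provenance = list(high = list(label = "high", n = length(hiIds)),
                        low = list(label = "low", n = length(loIds))))
}

#' Decision variable and call for a single signature profile
#'
#' The core of the classifier. The profile's Pearson correlation with the
#' high and with the low prototype gives `cor_high` and `cor_low`; the
#' decision variable is their ratio `d = cor_high / cor_low`. The call is
#' made by the comparison `cor_high >= cor_low` (ties call "high"). When
#' `cor_low > 0` the comparison coincides with the textbook rule `d >= 1`;
#' when `cor_low <= 0` the ratio rule is not sign-safe and the comparison
#' governs. A zero `cor_low` yields a signed-infinity `d` sentinel.
#'
#' @param profile numeric vector of the sample's signature-gene expression,
#'   either unnamed in signature order or named by gene ID.
#' @param prototypes a [PrototypePair-class].
#' @return list with `cor_high`, `cor_low`, `d` and `call` ("high"/"low").
#' @examples
#' sig <- GeneSignature("s", c("a", "b", "c"))
#' p <- new("PrototypePair", signature = sig, high = c(1, 2, 3),
#'          low = c(3, 2, 1), provenance = list())
#' decisionVariable(c(1, 2, 3), p)
#' @export
decisionVariable <- function(profile, prototypes) {
  stopifnot(is(prototypes, "PrototypePair"))
  ids <- prototypes@signature@geneIds
  if (!is.null(names(profile))) {
    .checkPresent(ids, names(profile), "gene in profile")
    profile <- profile[ids]
  } else if (length(profile) != length(ids)) {
    stop("profile length ", length(profile),
         " does not match signature size ", length(ids))
  }
  profile <- as.numeric(profile)
  if (!all(is.finite(profile))) stop("profile contains non-finite values")
  if (length(unique(profile)) < 2L)
    stop("undefined correlation: constant profile")
  corHigh <- stats::cor(profile, prototypes@high)
  corLow <- stats::cor(profile, prototypes@low)
  d <- if (corLow == 0) {
    if (corHigh >= 0) Inf else -Inf
  } else corHigh / corLow
  list(cor_high = corHigh, cor_low = corLow, d = d,
       call = if (corHigh >= corLow) "high" else "low")
}

#' Classify every sample of a cohort against fixed prototypes
#'
#' Applies [decisionVariable()] to each sample. The prototypes are NOT
#' refit, so prototypes trained on one cohort can be carried to others
#' (e.g. reference prototypes from a patient cohort applied to healthy
#' controls). A sample whose profile fails (e.g. constant) is reported with
#' NA values and a warning, never silently skipped.
#'
#' @param x matrix or SummarizedExperiment containing at least the
#'   signature genes.
#' @param prototypes a [PrototypePair-class] (carries its signature).
#' @return a [S4Vectors::DataFrame] with columns `sample_id`, `cor_high`,
#'   `cor_low`, `d`, `call`; its `metadata()` holds the summary list
#'   `nHigh`, `nLow`, `fractionHigh`.
#' @export
classifyCohort <- function(x, prototypes) {
  stopifnot(is(prototypes, "PrototypePair"))
  ids <- prototypes@signature@geneIds
  m <- .exprs(x)
  missing <- setdiff(ids, rownames(m))
  if (length(missing) == length(ids))
    stop("none of the signature genes are present in the matrix")
  if (length(missing))
    stop("signature gene(s) absent from matrix: ",
         paste(missing, collapse = ", "))
  m <- m[ids, , drop = FALSE]
  n <- ncol(m)
  recs <- lapply(seq_len(n), function(j) {
    tryCatch(decisionVariable(m[, j], prototypes),
             error = function(e) {
               warning("sample '", colnames(m)[j], "' not classified: ",
                       conditionMessage(e))
               list(cor_high = NA_real_, cor_low = NA_real_, d = NA_real_,
                    call = NA_character_)
             })
  })
  out <- S4Vectors::DataFrame(
    sample_id = colnames(m),
    cor_high = vapply(recs, `[[`, 0, "cor_high"),
    cor_low = vapply(recs, `[[`, 0, "cor_low"),
    d = vapply(recs, `[[`, 0, "d"),
    call = vapply(recs, `[[`, "", "call"))
  nHigh <- sum(out$call == "high", na.rm = TRUE)
  nLow <- sum(out$call == "low", na.rm = TRUE)
  S4Vectors::metadata(out) <- list(
    nHigh = nHigh, nLow = nLow,
    fractionHigh = nHigh / max(nHigh + nLow, 1L),
    provenance = prototypes@provenance)
  out
}

#' One-cohort workflow: bootstrap, build prototypes, classify
#'
#' Convenience composition of [bootstrapGroups()], [buildPrototypes()] and
#' [classifyCohort()] on a single cohort — the typical first analysis of a
#' new dataset. The pipeline contains no randomness, so two runs on the
#' same input give identical output.
#'
#' @param x matrix or SummarizedExperiment.
#' @param signature a [GeneSignature-class].
#' @param ... passed to [bootstrapGroups()] (linkage, distance).
#' @return list with `prototypes`, `records` (see [classifyCohort()]) and
#'   `groups` (the bootstrap groups).
#' @export
fitAndClassify <- function(x, signature, ...) {
  groups <- bootstrapGroups(x, signature, ...)
  prototypes <- buildPrototypes(x, signature, groups)
  records <- classifyCohort(x, prototypes)
  list(prototypes = prototypes, records = records, groups = groups)
}
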