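#' Classical mean-expression signature score
#'
#' The widely used alternative to the correlation-based call: a per-sample
#' score equal to the arithmetic mean of the signature genes' log2
#' expression. Given a matrix, returns one score per sample; given a bare
#' numeric profile, returns its mean.
#'
#' @param x matrix, SummarizedExperiment, or numeric profile vector.
#' @param signature a [GeneSignature-class]; required unless `x` is a bare
#'   profile.
#' @return named numeric vector of scores (or a single number).
#' @export
meanScore <- function(x, signature = NULL) {
  if (is.numeric(x) && is.null(dim(x))) {
    if (!all(is.finite(x))) stop("profile contains non-finite values")
    return(mean(x))
  }
  stopifnot(is(signature, "GeneSignature"))
  m <- .exprs(subsetExpression(x, genes = signature))
  colMeans(m)
}

#' Healthy-control 95% upper limit for the mean score
#'
#' The conventional positivity threshold of the mean-expression score:
#' mean of the healthy-control scores plus 1.96 times their sample standard
#' deviation (n - 1 denominator). Downstream, a score at or above the
#' threshold is called "high".
#'
#' @param hcScores numeric vector of healthy-control mean scores (>= 2).
#' @return the threshold (log2 units).
#' @examples
#' hcThreshold(c(9, 10, 11))  # 10 + 1.96 * 1
#' @export
hcThreshold <- function(hcScores) {
  hcScores <- as.numeric(hcScores)
  if (length(hcScores) < 2L)
    stop("need at least 2 healthy-control scores to estimate an SD")
  if (!all(is.finite(hcScores))) stop("scores must be finite")
  mean(hcScores) + 1.96 * stats::sd(hcScores)
}

#' Head-to-head comparison of the correlation call and the mean score
#'
#' Joins the classifier's per-sample decision records with mean-expression
#' scores, thresholds the scores at a healthy-control limit (score >=
#' threshold is "high"), and reports: the Spearman rank correlation between
#' the decision variable d and the mean score (average ranks for ties;
#' exact p by enumeration for n <= 9, large-sample t approximation above),
#' the 2 x 2 agreement table of the two calls, and the fraction of samples
#' on which the calls disagree. The two discordant quadrants (high score /
#' low call and vice versa) are flagged per sample in the records.
#'
#' @param records decision records from [classifyCohort()] (needs columns
#'   `sample_id`, `d`, `call`).
#' @param scores named numeric vector of mean scores for the same samples.
#' @param threshold mean-score positivity threshold, e.g. [hcThreshold()].
#' @return a [ScoreComparison-class].
#' @export
compareMethods <- function(records, scores, threshold) {
  if (is.null(names(scores)))
    stop("'scores' must be named by sample ID")
  idsR <- records$sample_id
  idsS <- names(scores)
  if (!setequal(idsR, idsS)) {
    onlyR <- setdiff(idsR, idsS)
    onlyS <- setdiff(idsS, idsR)
    stop("sample sets differ; only in records: ",
         paste(onlyR, collapse = ", "), "; only in scores: ",
         paste(onlyS, collapse = ", "))
  }
  scores <- scores[idsR]
  ok <- !is.na(records$call)
  d <- records$d[ok]
  sc <- scores[ok]
  callCabs <- records$call[ok]
  callScore <- unname(ifelse(sc >= threshold, "high", "low"))

  n <- length(d)
  # exact enumeration is only defined without ties; average ranks plus the
  # large-sample t approximation otherwise
  exact <- n <= 9 && !anyDuplicated(d) && !anyDuplicated(sc)
  ct <- stats::cor.test(d, sc, method = "spearman",
                        exact = exact, alternative = "two.sided")
  tab <- table(factor(callCabs, c("high", "low")),
               factor(callScore, c("high", "low")),
               dnn = c("cabs", "meanscore"))
  disc <- callCabs != callScore
  recs <- S4Vectors::DataFrame(
    sample_id = idsR[ok], mean_score = unname(sc), d = d,
    call_meanscore = callScore, call_cabs = callCabs, discordant = disc)
  new("ScoreComparison", records = recs,
      threshold = as.numeric(threshold),
      agreementFraction = mean(!disc),
      discordanceFraction = mean(disc),
      spearmanRho = unname(ct$estimate),
      spearmanP = ct$p.value,
      table = tab)
}
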