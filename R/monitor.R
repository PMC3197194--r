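#' Pair before/after decision records by patient
#'
#' Joins two sets of per-sample decision records (e.g. baseline and
#' 6-month follow-up under treatment) through a metadata table linking each
#' sample to a patient (`pair_id`) and a timepoint. Strata are assigned
#' from the BEFORE-treatment call, so a patient whose call flips during
#' follow-up stays in their baseline stratum. Unpaired samples are reported
#' in a warning and in the `"unpaired"` attribute, then excluded.
#'
#' @param before,after decision records from [classifyCohort()].
#' @param metadata data.frame/DataFrame with columns `sample_id`,
#'   `pair_id`, `timepoint`.
#' @param beforeLabel,afterLabel the timepoint labels (defaults "before",
#'   "after"); any other label in the metadata is an error.
#' @return data.frame with columns `patient_id`, `d_before`, `d_after`,
#'   `stratum` (the baseline call).
#' @export
pairSamples <- function(before, after, metadata,
                        beforeLabel = "before", afterLabel = "after") {
  md <- as.data.frame(metadata)
  need <- c("sample_id", "pair_id", "timepoint")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(md$timepoint), c(beforeLabel, afterLabel))
  if (length(bad))
    stop("unknown timepoint label(s): ", paste(bad, collapse = ", "))
  for (tp in c(beforeLabel, afterLabel)) {
    sub <- md[md$timepoint == tp, ]
    if (anyDuplicated(sub$pair_id))
      stop("duplicate pair_id within timepoint '", tp, "': ",
           paste(unique(sub$pair_id[duplicated(sub$pair_id)]),
                 collapse = ", "))
  }
  lookup <- function(records, tp) {
    ids <- records$sample_id
    .checkPresent(ids, md$sample_id, "sample in metadata")
    sub <- md[match(ids, md$sample_id), ]
    wrong <- sub$timepoint != tp
    if (any(wrong))
      stop("sample(s) supplied as '", tp, "' but labelled '",
           paste(unique(sub$timepoint[wrong]), collapse = "','"),
           "' in metadata: ", paste(ids[wrong], collapse = ", "))
    data.frame(pair_id = sub$pair_id, d = records$d,
               call = records$call, stringsAsFactors = FALSE)
  }
  b <- lookup(before, beforeLabel)
  a <- lookup(after, afterLabel)
  shared <- intersect(b$pair_id, a$pair_id)
  orphans <- c(setdiff(b$pair_id, shared), setdiff(a$pair_id, shared))
  if (length(orphans))
    warning("unpaired patient(s) excluded: ",
            paste(orphans, collapse = ", "))
  b <- b[match(shared, b$pair_id), ]
  a <- a[match(shared, a$pair_id), ]
  out <- data.frame(patient_id = shared,
                    d_before = b$d, d_after = a$d,
                    stratum = b$call, stringsAsFactors = FALSE)
  attr(out, "unpaired") <- orphans
  out
}

#' Wilcoxon signed-rank test for paired differences
#'
#' Two-sided one-sample signed-rank test on a vector of paired differences.
#' Zero differences are dropped before ranking (the original zero-handling
#' procedure); absolute differences are ranked with average ranks for ties.
#' For up to 12 nonzero differences the p-value is exact, computed from the
#' full null distribution of W over all 2^n sign assignments (enumeration
#' handles tied ranks correctly, unlike the usual exact tables); above 12 a
#' normal approximation with tie correction and continuity correction is
#' used.
#'
#' @param differences numeric vector of paired differences.
#' @return list with `statistic` (W, the sum of ranks of positive
#'   differences), `p.value`, `n` (number of nonzero differences) and
#'   `method` ("exact" or "normal approximation").
#' @examples
#' wilcoxonSignedRank(c(0.3, 0.1, 0.2))  # all positive, n = 3: p = 0.25
#' @export
wilcoxonSignedRank <- function(differences) {
  d <- as.numeric(differences)
  if (!all(is.finite(d))) stop("differences must be finite")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop("no information: all differences are zero")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12L) {
    # Exact null distribution of 2W by convolution over the doubled ranks
    # (doubling makes average ranks integral). Each rank enters the sum
    # independently with probability 1/2 under the null.
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- numeric(total + 1L)
    counts[1L] <- 1
    for (ri in r2)
      counts <- counts + c(rep(0, ri), counts[seq_len(total + 1L - ri)])
    w2 <- as.integer(round(2 * W))
    pLess <- sum(counts[seq_len(w2 + 1L)]) / 2^n
    pGreater <- sum(counts[seq.int(w2 + 1L, total + 1L)]) / 2^n
    p <- min(1, 2 * min(pLess, pGreater))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    num <- W - mu
    z <- (num - sign(num) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  list(statistic = W, p.value = p, n = n, method = method)
}

#' Monitor the decision variable within one baseline stratum
#'
#' Applies the signed-rank test to the within-patient change of the
#' decision variable (`d_after - d_before`) among the pairs of one baseline
#' stratum, the monitored quantity of the longitudinal analysis. The
#' direction is the sign of the median paired difference. When every
#' difference is zero the lower-level test has no information; at this
#' level the result is reported as direction "none" with p = 1, so
#' pipelines keep running.
#'
#' @param pairs data.frame from [pairSamples()].
#' @param stratum baseline stratum label to keep ("high"/"low"), or NULL
#'   for all pairs.
#' @return a [PairedMonitoringResult-class].
#' @export
monitorStratum <- function(pairs, stratum = NULL) {
  label <- stratum %||% "all"
  if (!is.null(stratum)) pairs <- pairs[pairs$stratum == stratum, ]
  if (nrow(pairs) == 0L) stop("empty stratum: ", label)
  diffs <- pairs$d_after - pairs$d_before
  md <- stats::median(diffs)
  direction <- if (md > 0) "increase" else if (md < 0) "decrease" else "none"
  if (all(diffs == 0)) {
    w <- NA_real_
    p <- 1
  } else {
    t <- wilcoxonSignedRank(diffs)
    w <- t$statistic
    p <- t$p.value
  }
  new("PairedMonitoringResult",
      stratumLabel = label,
      pairs = pairs[, c("patient_id", "d_before", "d_after")],
      n = nrow(pairs), wStatistic = w, pValue = p, direction = direction)
}
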