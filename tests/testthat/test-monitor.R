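mkMeta <- function(pairIds, timepoint) {
  data.frame(sample_id = paste0(pairIds, "_", timepoint),
             pair_id = pairIds, timepoint = timepoint,
             stringsAsFactors = FALSE)
}

mkRecords <- function(pairIds, timepoint, d, call = NULL) {
  data.frame(sample_id = paste0(pairIds, "_", timepoint),
             d = d, call = call %||% ifelse(d >= 1, "high", "low"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("pairing joins on pair_id, reports orphans, strata from baseline", {
  before <- mkRecords(c("P1", "P2", "P3", "P4"), "before",
                      c(1.5, 0.6, 1.2, 0.9))
  after <- mkRecords(c("P1", "P2", "P3"), "after", c(1.1, 0.8, 1.4))
  meta <- rbind(mkMeta(c("P1", "P2", "P3", "P4"), "before"),
                mkMeta(c("P1", "P2", "P3"), "after"))
  expect_warning(pairs <- pairSamples(before, after, meta), "P4")
  expect_identical(nrow(pairs), 3L)
  expect_identical(attr(pairs, "unpaired"), "P4")
  expect_identical(pairs$stratum, c("high", "low", "high"))
  expect_equal(pairs$d_after - pairs$d_before, c(-0.4, 0.2, 0.2))
})

test_that("pairing rejects unknown timepoints and duplicate pair IDs", {
  before <- mkRecords("P1", "before", 1.2)
  after <- mkRecords("P1", "after", 1.0)
  badMeta <- rbind(mkMeta("P1", "baseline"), mkMeta("P1", "after"))
  expect_error(pairSamples(before, after, badMeta), "unknown timepoint")

  # swapped supplies: the before records carry an 'after' timepoint
  meta <- rbind(mkMeta("P1", "before"), mkMeta("P1", "after"))
  expect_error(pairSamples(after, before, meta), "supplied as")

  dupMeta <- rbind(mkMeta(c("P1", "P1"), "before"), mkMeta("P1", "after"))
  dupMeta$sample_id[2] <- "P1b_before"
  expect_error(pairSamples(before, after, dupMeta), "duplicate pair_id")
})

test_that("signed-rank exact p-values match enumeration", {
  # n = 3, all positive: only the all-positive assignment reaches W = 6
  r <- wilcoxonSignedRank(c(0.3, 0.1, 0.2))
  expect_equal(r$statistic, 6)
  expect_equal(r$p.value, 0.25)  # 2 * (1/8)
  expect_identical(r$method, "exact")

  # antisymmetric differences sit at the null centre
  r2 <- wilcoxonSignedRank(c(1, -1, 2, -2, 3, -3))
  expect_equal(r2$p.value, 1)

  # random fixtures incl. ties vs 2^n enumeration
  for (seed in 1:8) {
    set.seed(seed)
    d <- round(rnorm(10), 1)  # rounding forces tied |d| now and then
    d <- d[d != 0]
    if (length(d) < 2) next
    got <- wilcoxonSignedRank(d)
    want <- bfWilcoxonExact(d)
    expect_equal(got$statistic, want$statistic)
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("signed-rank matches wilcox.test where both are exact", {
  for (seed in 11:16) {
    set.seed(seed)
    d <- rnorm(12)  # continuous: no ties, no zeros
    got <- wilcoxonSignedRank(d)
    want <- wilcox.test(d, exact = TRUE)
    expect_equal(got$statistic, unname(want$statistic))
    expect_equal(got$p.value, want$p.value)
  }
})

test_that("large-sample approximation matches the corrected normal test", {
  set.seed(21)
  d <- rnorm(25, 0.3)
  got <- wilcoxonSignedRank(d)
  expect_identical(got$method, "normal approximation")
  want <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(got$statistic, unname(want$statistic))
  expect_equal(got$p.value, want$p.value)
})

test_that("signed-rank symmetry: flipping all signs complements W", {
  for (seed in 31:35) {
    set.seed(seed)
    d <- rnorm(9)
    a <- wilcoxonSignedRank(d)
    b <- wilcoxonSignedRank(-d)
    expect_equal(a$statistic + b$statistic, 9 * 10 / 2)
    expect_equal(a$p.value, b$p.value)
  }
})

test_that("zero differences are dropped; all-zero input is no information", {
  a <- wilcoxonSignedRank(c(0.5, 0, -0.2, 0))
  b <- wilcoxonSignedRank(c(0.5, -0.2))
  expect_equal(a$p.value, b$p.value)
  expect_identical(a$n, 2L)
  expect_error(wilcoxonSignedRank(c(0, 0, 0)), "no information")
})

test_that("stratum monitoring: boundaries and the all-zero policy", {
  pairs <- data.frame(patient_id = "P1", d_before = 1.2, d_after = 1.0,
                      stratum = "high", stringsAsFactors = FALSE)
  res <- monitorStratum(pairs, "high")
  expect_equal(res@pValue, 1)  # exact floor at n = 1
  expect_identical(res@direction, "decrease")

  frozen <- data.frame(patient_id = c("P1", "P2"),
                       d_before = c(1, 2), d_after = c(1, 2),
                       stratum = "low", stringsAsFactors = FALSE)
  resF <- monitorStratum(frozen, "low")
  expect_identical(resF@direction, "none")
  expect_equal(resF@pValue, 1)
  expect_true(is.na(resF@wStatistic))

  expect_error(monitorStratum(pairs, "low"), "empty stratum")
})

test_that("an 11+11 paired synthetic cohort stratifies and detects the designed effect", {
  train <- generateCohort(cohortDesign(geneSeed = 101L), seed = 7)
  sig <- S4Vectors::metadata(train)$signature
  prototypes <- fitAndClassify(train, sig)$prototypes
  pd <- cohortDesign(groups = data.frame(label = c("high", "low"),
                                         nSamples = c(11L, 11L),
                                         rho = c(0.63, 0.33),
                                         meanShift = c(2, 0)),
                     geneSeed = 101L)
  pc <- pairedCohort(pd, seed = 11)
  recB <- classifyCohort(pc$before, prototypes)
  recA <- classifyCohort(pc$after, prototypes)
  pairs <- pairSamples(recB, recA, pc$metadata)
  expect_identical(as.integer(table(pairs$stratum)[c("high", "low")]),
                   c(11L, 11L))
  hi <- monitorStratum(pairs, "high")
  expect_identical(hi@direction, "decrease")
  expect_lt(hi@pValue, 0.05)
  lo <- monitorStratum(pairs, "low")
  expect_identical(lo@direction, "increase")
})
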