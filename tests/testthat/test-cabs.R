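test_that("bootstrap recovers well-separated groups and labels by expression", {
  m <- twoBlobMatrix(nPerGroup = 10, seed = 2)
  sig <- sigFor(m)
  groups <- bootstrapGroups(m, sig)
  expect_setequal(sampleIds(groups$high), sprintf("hi%02d", 1:10))
  expect_setequal(sampleIds(groups$low), sprintf("lo%02d", 1:10))
  # labelling rule: the cluster with the larger mean signature expression
  # is "high"; moving the shape-A cluster down flips the labels
  m2 <- m
  m2[, 1:10] <- m[, 1:10] - 20  # shape-A cluster now the LOW-expression one
  groups2 <- bootstrapGroups(m2, sig)
  expect_setequal(sampleIds(groups2$high), sprintf("lo%02d", 1:10))
})

test_that("bootstrap edge cases: two samples, identical profiles, zero variance", {
  m <- twoBlobMatrix(nPerGroup = 1, seed = 3)
  expect_warning(groups <- bootstrapGroups(m, sigFor(m)), "size 1")
  expect_length(sampleIds(groups$high), 1L)

  const <- matrix(rep(c(1, 2, 3), 4), 3, 4,
                  dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  expect_error(bootstrapGroups(const, GeneSignature("s", c("a", "b", "c"))),
               "degenerate")
  flat <- const
  flat[, 1] <- 5
  expect_error(bootstrapGroups(flat, GeneSignature("s", c("a", "b", "c"))),
               "zero-variance")
})

test_that("prototypes are per-gene group medians in signature order", {
  # single-sample group: prototype is that sample's profile
  m <- randMatrix(6, 4, seed = 21)
  sig <- sigFor(m)
  p <- buildPrototypes(m, sig, list(high = "s001", low = c("s002", "s003")))
  expect_equal(unname(prototypeHigh(p)), unname(m[, "s001"]))

  # median robustness: (1, 5, 100) -> 5
  m2 <- rbind(gA = c(1, 5, 100, 7, 8),
              gB = c(2, 3, 4, 5, 6),
              gC = c(0, 1, 2, 3, 4))
  colnames(m2) <- c("x", "y", "z", "u", "v")
  p2 <- buildPrototypes(m2, GeneSignature("s", c("gA", "gB", "gC")),
                        list(high = c("x", "y", "z"), low = c("u", "v")))
  expect_equal(unname(prototypeHigh(p2))[1], 5)

  # brute-force oracle on a 35-gene, 20+20-sample fixture
  m3 <- randMatrix(35, 40, seed = 22)
  hi <- colnames(m3)[1:20]
  lo <- colnames(m3)[21:40]
  p3 <- buildPrototypes(m3, sigFor(m3), list(high = hi, low = lo))
  for (j in c(1, 17, 35)) {
    expect_equal(unname(prototypeHigh(p3))[j], bfMedian(m3[j, hi]))
    expect_equal(unname(prototypeLow(p3))[j], bfMedian(m3[j, lo]))
  }
  # signature order governs entry order
  revSig <- GeneSignature("r", rev(rownames(m3)))
  pr <- buildPrototypes(m3, revSig, list(high = hi, low = lo))
  expect_equal(unname(prototypeHigh(pr)), rev(unname(prototypeHigh(p3))))

  expect_error(buildPrototypes(m, sig, list(high = "s001", low = "s001")),
               "overlap")
  expect_error(buildPrototypes(m, sig, list(high = "s001",
                                            low = character(0))),
               "non-empty")
})

test_that("decision variable follows the correlation-comparison rule", {
  sig <- GeneSignature("s", c("a", "b", "c"))
  p <- new("PrototypePair", signature = sig,
           high = c(1, 2, 3), low = c(3, 2, 1), provenance = list())
  # profile identical to the high prototype
  r <- decisionVariable(c(1, 2, 3), p)
  expect_equal(r$cor_high, 1)
  expect_equal(r$cor_low, -1)
  expect_equal(r$d, -1)       # ratio rule would say "low"...
  expect_identical(r$call, "high")  # ...but the comparison governs

  r2 <- decisionVariable(c(3, 2, 1), p)
  expect_identical(r2$call, "low")

  # named profiles are reordered to signature order
  r3 <- decisionVariable(c(c = 3, a = 1, b = 2), p)
  expect_equal(r3$cor_high, 1)

  expect_error(decisionVariable(c(5, 5, 5), p), "constant")
  expect_error(decisionVariable(c(1, 2), p), "signature size")
})

test_that("decision correlations match the covariance-definition oracle", {
  m <- randMatrix(35, 12, seed = 33)
  p <- randPrototypes(m, seed = 34)
  for (j in 1:6) {
    r <- decisionVariable(m[, j], p)
    expect_equal(r$cor_high, bfPearson(m[, j], unname(prototypeHigh(p))))
    expect_equal(r$cor_low, bfPearson(m[, j], unname(prototypeLow(p))))
    expect_true(abs(r$cor_high) <= 1 && abs(r$cor_low) <= 1)
  }
})

test_that("the call is invariant to affine rescaling of the profile", {
  m <- randMatrix(20, 8, seed = 41)
  p <- randPrototypes(m, seed = 42)
  for (i in 1:10) {
    set.seed(100 + i)
    prof <- rnorm(20)
    a <- runif(1, 0.1, 5)
    b <- rnorm(1, 0, 10)
    r1 <- decisionVariable(prof, p)
    r2 <- decisionVariable(a * prof + b, p)
    expect_equal(r1$cor_high, r2$cor_high)
    expect_equal(r1$cor_low, r2$cor_low)
    expect_identical(r1$call, r2$call)
  }
})

test_that("swapping prototype labels inverts calls and reciprocates d", {
  m <- randMatrix(15, 30, seed = 51)
  sig <- sigFor(m)
  hi <- colnames(m)[1:15]
  lo <- colnames(m)[16:30]
  p <- buildPrototypes(m, sig, list(high = hi, low = lo))
  pSwap <- buildPrototypes(m, sig, list(high = lo, low = hi))
  rec <- classifyCohort(m, p)
  recSwap <- classifyCohort(m, pSwap)
  expect_identical(recSwap$call,
                   ifelse(rec$call == "high", "low", "high"))
  both <- rec$cor_high > 0 & rec$cor_low > 0
  expect_equal(recSwap$d[both], 1 / rec$d[both])
})

test_that("cohort classification is prototype-faithful and permutation-equivariant", {
  m <- randMatrix(10, 6, seed = 61)
  sig <- sigFor(m)
  p <- buildPrototypes(m, sig, list(high = c("s001", "s002"),
                                    low = c("s004", "s005")))
  cohort <- cbind(protoHigh = unname(prototypeHigh(p)),
                  protoLow = unname(prototypeLow(p)))
  rownames(cohort) <- geneIds(sig)
  rec <- classifyCohort(cohort, p)
  expect_identical(rec$call, c("high", "low"))
  expect_equal(rec$cor_high[1], 1)
  expect_equal(rec$cor_low[2], 1)

  perm <- m[, c(4, 1, 6, 2, 3, 5)]
  r1 <- classifyCohort(m, p)
  r2 <- classifyCohort(perm, p)
  expect_equal(as.data.frame(r2),
               as.data.frame(r1)[match(r2$sample_id, r1$sample_id), ],
               ignore_attr = TRUE)

  other <- randMatrix(4, 3, seed = 62)
  rownames(other) <- paste0("zz", 1:4)
  expect_error(classifyCohort(other, p), "none of the signature genes")
  partial <- m[1:9, ]
  expect_error(classifyCohort(partial, p), "g010")
})

test_that("a failing sample is reported, not skipped", {
  m <- randMatrix(8, 4, seed = 71)
  p <- randPrototypes(m, seed = 72)
  m[, 2] <- 3  # constant profile
  expect_warning(rec <- classifyCohort(m, p), "s002")
  expect_identical(nrow(rec), 4L)
  expect_true(is.na(rec$call[2]))
  expect_false(anyNA(rec$call[-2]))
})

test_that("fit-and-classify recovers generator labels and is deterministic", {
  se <- generateCohort(cohortDesign(nBackground = 0), seed = 5)
  sig <- S4Vectors::metadata(se)$signature
  truth <- SummarizedExperiment::colData(se)$group
  fit1 <- fitAndClassify(se, sig)
  expect_gte(mean(fit1$records$call == truth), 0.95)
  fit2 <- fitAndClassify(se, sig)
  expect_equal(as.data.frame(fit1$records), as.data.frame(fit2$records))

  # structureless cohort still completes, with near-chance calls
  flat <- cohortDesign(nBackground = 0,
                       groups = data.frame(label = c("a", "b"),
                                           nSamples = c(30L, 30L),
                                           rho = c(0, 0),
                                           meanShift = c(0, 0)))
  seFlat <- generateCohort(flat, seed = 6)
  fitFlat <- fitAndClassify(seFlat, S4Vectors::metadata(seFlat)$signature)
  frac <- S4Vectors::metadata(fitFlat$records)$fractionHigh
  expect_gte(frac, 0.1)
  expect_lte(frac, 0.9)
})

test_that("prototypes survive a JSON round trip", {
  m <- randMatrix(12, 10, seed = 81)
  p <- randPrototypes(m, seed = 82)
  f <- tempfile(fileext = ".json")
  writePrototypes(p, f)
  p2 <- readPrototypes(f)
  expect_identical(geneIds(p2), geneIds(p))
  expect_equal(p2@high, p@high)
  expect_equal(p2@low, p@low)
  rec1 <- classifyCohort(m, p)
  rec2 <- classifyCohort(m, p2)
  expect_equal(as.data.frame(rec1), as.data.frame(rec2))
})
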