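#' Factor loading achieving a target pairwise correlation
#'
#' In the one-factor model `x = mu + lambda * f + eps` with `f ~ N(0, 1)`
#' and `eps ~ N(0, noiseSd^2)` independent, every pair of genes sharing the
#' factor has Pearson correlation `lambda^2 / (lambda^2 + noiseSd^2)`.
#' Inverting gives the loading that hits a requested correlation exactly:
#' `lambda = noiseSd * sqrt(rho / (1 - rho))`.
#'
#' @param rho target pairwise correlation in [0, 1).
#' @param noiseSd residual standard deviation (default 1).
#' @return the loading lambda (vectorised over `rho`).
#' @examples
#' loadingForRho(0.5)           # 1
#' loadingForRho(0.63)          # sqrt(0.63/0.37) ~ 1.3049
#' @export
loadingForRho <- function(rho, noiseSd = 1) {
  if (any(rho < 0 | rho >= 1)) stop("rho must lie in [0, 1)")
  if (any(noiseSd <= 0)) stop("noiseSd must be positive")
  noiseSd * sqrt(rho / (1 - rho))
}

#' Construct a synthetic cohort design
#'
#' The default design emulates a two-group cohort in the regime the
#' classifier targets: an activated group whose 35 signature genes share a
#' latent factor giving pairwise correlation 0.63 and sit 2 log2 units
#' (4-fold, on signature average) above baseline, and a quiescent group at
#' correlation 0.33 with no shift, plus uncorrelated background genes. See
#' [generateCohort()] for the generative model and the methods vignette for
#' the rationale behind each default.
#'
#' @param mSignature number of signature genes (default 35).
#' @param nBackground number of background genes (default 200).
#' @param groups data.frame with columns `label`, `nSamples`, `rho`,
#'   `meanShift`.
#' @param baselineMean signature-average baseline log2 expression
#'   (default 8).
#' @param noiseSd per-gene residual SD in log2 units (default 1).
#' @param loadingJitter SD of per-gene loading heterogeneity (default 0.1).
#' @param geneBaselineSd SD of fixed per-gene baseline offsets
#'   (default 1.5 log2 units, the typical spread of expressed genes).
#' @param responseSpread half-width of the uniform per-gene activation
#'   response weights around 1 (default 1: weights in [0, 2], so genes
#'   range from unresponsive to strongly induced).
#' @param seed optional integer seed stored with the design.
#' @param geneSeed optional integer seed for the gene-level parameters;
#'   designs sharing a geneSeed describe cohorts over the same genes, so
#'   prototypes transfer between them (see [CohortDesign-class]).
#' @return a [CohortDesign-class].
#' @export
cohortDesign <- function(mSignature = 35, nBackground = 200,
                         groups = data.frame(
                           label = c("high", "low"),
                           nSamples = c(50L, 50L),
                           rho = c(0.63, 0.33),
                           meanShift = c(2, 0),
                           stringsAsFactors = FALSE),
                         baselineMean = 8, noiseSd = 1,
                         loadingJitter = 0.1, geneBaselineSd = 1.5,
                         responseSpread = 1, seed = NULL,
                         geneSeed = NULL) {
  groups$nSamples <- as.integer(groups$nSamples)
  new("CohortDesign",
      mSignature = as.integer(mSignature),
      nBackground = as.integer(nBackground),
      groups = as.data.frame(groups),
      baselineMean = as.numeric(baselineMean),
      noiseSd = as.numeric(noiseSd),
      loadingJitter = as.numeric(loadingJitter),
      geneBaselineSd = as.numeric(geneBaselineSd),
      responseSpread = as.numeric(responseSpread),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      geneSeed = if (is.null(geneSeed)) NA_integer_ else
        as.integer(geneSeed))
}

## Draw the cohort-level gene parameters shared by all groups/timepoints.
## Centring conventions (offsets mean 0, weights mean 1, jitter mean 0) pin
## the realised cohort-level targets to the design values; see vignette.
.geneParams <- function(design) {
  if (!is.na(design@geneSeed))
    return(.withSeed(design@geneSeed, .drawGeneParams(design)))
  .drawGeneParams(design)
}

.drawGeneParams <- function(design) {
  m <- design@mSignature
  b <- stats::rnorm(m, 0, design@geneBaselineSd)
  b <- b - mean(b)
  w <- stats::runif(m, 1 - design@responseSpread, 1 + design@responseSpread)
  w <- pmax(w, 0)
  w <- w / mean(w)
  jit <- stats::rnorm(m, 0, design@loadingJitter)
  jit <- jit - mean(jit)
  bg <- stats::rnorm(design@nBackground, 0, design@geneBaselineSd)
  list(baseline = b, weight = w, jitter = jit, bgBaseline = bg)
}

## Standardised factor scores: exact mean 0 / variance 1 in the realised
## draw, so the empirical inter-gene correlation concentrates on the
## closed-form target instead of drifting with the factor's sampled
## variance.
.factorScores <- function(n) {
  f <- stats::rnorm(n)
  if (n == 1L) return(0)
  (f - mean(f)) / stats::sd(f)
}

## One group's signature block (genes x samples).
.groupBlock <- function(design, pars, rho, shift, n) {
  lambda <- loadingForRho(rho, design@noiseSd)
  f <- .factorScores(n)
  design@baselineMean + pars$baseline + pars$weight * shift +
    outer(lambda + pars$jitter, f) +
    matrix(stats::rnorm(design@mSignature * n, 0, design@noiseSd),
           design@mSignature, n)
}

.assembleCohort <- function(design, pars, blocks, sampleIds, groupLabels,
                            extraColData = list()) {
  sig <- do.call(cbind, blocks)
  bg <- design@baselineMean + pars$bgBaseline +
    matrix(stats::rnorm(design@nBackground * ncol(sig), 0, design@noiseSd),
           design@nBackground, ncol(sig))
  m <- rbind(sig, bg)
  rownames(m) <- c(sprintf("SIG%03d", seq_len(design@mSignature)),
                   sprintf("BG%04d", seq_len(design@nBackground)))
  colnames(m) <- sampleIds
  cd <- S4Vectors::DataFrame(group = groupLabels, row.names = sampleIds)
  for (nm in names(extraColData)) cd[[nm]] <- extraColData[[nm]]
  rd <- S4Vectors::DataFrame(
    role = rep(c("signature", "background"),
               c(design@mSignature, design@nBackground)),
    row.names = rownames(m))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd, rowData = rd)
  S4Vectors::metadata(se) <- list(
    design = design,
    signature = GeneSignature("signature",
                              sprintf("SIG%03d", seq_len(design@mSignature))),
    geneParams = pars)
  se
}

#' Generate a synthetic expression cohort
#'
#' Generative model, per sample `s` of group `g` and signature gene `j`:
#' \deqn{x_{js} = \mu + b_j + w_j \Delta_g + (\lambda_g + u_j) f_s +
#'   \varepsilon_{js}}
#' where `mu` is the baseline mean, `b_j` fixed per-gene baseline offsets
#' (centred), `w_j` per-gene activation response weights (mean 1) scaling
#' the group shift `Delta_g`, `lambda_g` the loading from [loadingForRho()]
#' so the population pairwise inter-gene correlation equals the group's
#' `rho`, `u_j` centred per-gene loading jitter, `f_s` standardised latent
#' activation scores, and `eps` Gaussian noise. Background genes are
#' independent Gaussians around their own fixed baselines. Everything is
#' reproducible from the seed.
#'
#' @param design a [CohortDesign-class].
#' @param seed integer seed (defaults to the design's stored seed).
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, the true group label in `colData()$group`, gene roles in
#'   `rowData()$role`, and the design, signature and drawn gene parameters
#'   in `metadata()`.
#' @examples
#' se <- generateCohort(cohortDesign(), seed = 1)
#' table(SummarizedExperiment::colData(se)$group)
#' @export
generateCohort <- function(design, seed = NULL) {
  stopifnot(is(design, "CohortDesign"))
  seed <- seed %||% (if (!is.na(design@seed)) design@seed else
    stop("no seed: supply one or store it in the design"))
  .withSeed(seed, {
    pars <- .geneParams(design)
    g <- design@groups
    blocks <- list()
    ids <- character(0)
    labels <- character(0)
    for (i in seq_len(nrow(g))) {
      blocks[[i]] <- .groupBlock(design, pars, g$rho[i], g$meanShift[i],
                                 g$nSamples[i])
      ids <- c(ids, sprintf("%s_%03d", g$label[i], seq_len(g$nSamples[i])))
      labels <- c(labels, rep(g$label[i], g$nSamples[i]))
    }
    .assembleCohort(design, pars, blocks, ids, labels)
  })
}

#' Generate a linked before/after paired cohort
#'
#' Fixture for longitudinal monitoring: the same patients are generated at
#' two timepoints sharing all cohort-level gene parameters (baselines,
#' response weights, jitter), while the "after" timepoint regenerates each
#' group's latent structure at a modified correlation target and mean
#' shift. The default effect emulates treatment damping the activation of
#' the activated group (rho 0.63 to 0.40, shift +2 to +1) and mildly
#' stimulating the quiescent group (rho 0.33 to 0.45, shift 0 to +0.5).
#'
#' @param design a [CohortDesign-class] describing the BEFORE state.
#' @param effect data.frame with columns `label`, `rhoAfter`,
#'   `meanShiftAfter`, one row per design group.
#' @param seed integer seed (defaults to the design's stored seed).
#' @return list with elements `before` and `after` (each as in
#'   [generateCohort()], with `pair_id` and `timepoint` in `colData`) and
#'   `metadata` (a data.frame linking sample IDs, pair IDs, timepoints and
#'   true groups, ready for [pairSamples()]).
#' @export
pairedCohort <- function(design,
                         effect = data.frame(
                           label = c("high", "low"),
                           rhoAfter = c(0.40, 0.45),
                           meanShiftAfter = c(1, 0.5),
                           stringsAsFactors = FALSE),
                         seed = NULL) {
  stopifnot(is(design, "CohortDesign"))
  g <- design@groups
  if (!all(c("label", "rhoAfter", "meanShiftAfter") %in% names(effect)))
    stop("effect must have columns label, rhoAfter, meanShiftAfter")
  if (!setequal(effect$label, g$label))
    stop("effect labels must match the design's group labels")
  if (any(effect$rhoAfter < 0 | effect$rhoAfter >= 1))
    stop("rhoAfter must lie in [0, 1)")
  effect <- effect[match(g$label, effect$label), ]
  seed <- seed %||% (if (!is.na(design@seed)) design@seed else
    stop("no seed: supply one or store it in the design"))
  .withSeed(seed, {
    pars <- .geneParams(design)
    nTot <- sum(g$nSamples)
    pids <- sprintf("P%03d", seq_len(nTot))
    pidByGroup <- split(pids, rep(seq_len(nrow(g)), g$nSamples))
    build <- function(tp, rhos, shifts) {
      blocks <- list()
      ids <- character(0)
      labels <- character(0)
      prs <- character(0)
      for (i in seq_len(nrow(g))) {
        blocks[[i]] <- .groupBlock(design, pars, rhos[i], shifts[i],
                                   g$nSamples[i])
        ids <- c(ids, paste0(pidByGroup[[i]], "_", tp))
        labels <- c(labels, rep(g$label[i], g$nSamples[i]))
        prs <- c(prs, pidByGroup[[i]])
      }
      .assembleCohort(design, pars, blocks, ids, labels,
                      extraColData = list(pair_id = prs,
                                          timepoint = rep(tp, length(ids))))
    }
    before <- build("before", g$rho, g$meanShift)
    after <- build("after", effect$rhoAfter, effect$meanShiftAfter)
    md <- rbind(
      as.data.frame(SummarizedExperiment::colData(before))[
        , c("group", "pair_id", "timepoint")],
      as.data.frame(SummarizedExperiment::colData(after))[
        , c("group", "pair_id", "timepoint")])
    md <- data.frame(sample_id = rownames(md), md,
                     row.names = NULL, stringsAsFactors = FALSE)
    list(before = before, after = after, metadata = md)
  })
}
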