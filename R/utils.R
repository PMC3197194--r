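`%||%` <- function(a, b) if (is.null(a)) b else a

## Extract the expression matrix (genes x samples, dimnames required) from
## either a plain matrix or a SummarizedExperiment (assay "exprs" preferred).
.exprs <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    nm <- SummarizedExperiment::assayNames(x)
    m <- if (!is.null(nm) && "exprs" %in% nm)
      SummarizedExperiment::assay(x, "exprs")
    else SummarizedExperiment::assay(x, 1)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stop("expected a matrix or SummarizedExperiment, got ", class(x)[1])
  }
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have gene row names and sample column names")
  if (anyDuplicated(rownames(m)))
    stop("duplicated gene IDs in expression matrix")
  if (anyDuplicated(colnames(m)))
    stop("duplicated sample IDs in expression matrix")
  storage.mode(m) <- "double"
  m
}

## Resolve a genes argument (GeneSignature or character) to an ID vector.
.geneIdsOf <- function(genes) {
  if (is(genes, "GeneSignature")) genes@geneIds else as.character(genes)
}

## Resolve a samples argument (SampleGroup or character) to an ID vector.
.sampleIdsOf <- function(samples) {
  if (is(samples, "SampleGroup")) samples@sampleIds else as.character(samples)
}

.checkPresent <- function(wanted, available, what) {
  missing <- setdiff(wanted, available)
  if (length(missing))
    stop("unknown ", what, ": ", paste(missing, collapse = ", "))
  invisible(TRUE)
}

## Run expr with a locally set RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Raw median absolute deviation (no consistency constant): the filter only
## ever compares MADs to their own median, so any constant would cancel.
.rawMad <- function(v) stats::median(abs(v - stats::median(v)))
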