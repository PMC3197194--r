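#' Read a log2 expression matrix from a delimited text file
#'
#' The expected layout is genes on rows and samples on columns: a header row
#' of sample IDs and a first column of gene IDs, with a numeric body. Values
#' are assumed to be already normalised log2 intensities; the package never
#' re-normalises. The header may either name the gene-ID column (one more
#' header field than data columns) or omit it.
#'
#' @param path path to the file.
#' @param format "auto" (default; by file extension), "tsv" or "csv".
#' @param metadata optional path to a sample metadata table (see
#'   [readSampleMetadata()]) or a data.frame with a `sample_id` column.
#' @param dropIncomplete if TRUE, genes containing missing values are
#'   dropped (with a message); by default missing values are an error, since
#'   every downstream statistic silently degrades under imputation.
#' @param transpose if TRUE the file is read as samples x genes and
#'   transposed; there is deliberately no auto-detection.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `exprs`, gene row names and sample column names; metadata columns (if
#'   supplied) in `colData`.
#' @examples
#' f <- system.file("extdata", "example_expression.tsv", package = "cabsig")
#' se <- readExpressionMatrix(f)
#' dim(se)
#' @export
readExpressionMatrix <- function(path, format = c("auto", "tsv", "csv"),
                                 metadata = NULL, dropIncomplete = FALSE,
                                 transpose = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  sep <- switch(format,
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    tsv = "\t", csv = ",")

  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("format error: need a header row and at least one gene row")
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- trimws(fields[[1L]])
  body <- fields[-1L]

  widths <- lengths(body)
  if (length(unique(widths)) != 1L)
    stop("format error: ragged rows (rows ",
         paste(which(widths != widths[1L]) + 1L, collapse = ", "),
         " have a different number of fields)")
  ncolBody <- widths[1L] - 1L
  if (ncolBody < 1L) stop("format error: no sample columns")

  if (length(header) == ncolBody + 1L) {
    sampleIds <- header[-1L]
  } else if (length(header) == ncolBody) {
    sampleIds <- header
  } else {
    stop("format error: header has ", length(header),
         " fields but data rows have ", ncolBody + 1L)
  }
  geneIds <- vapply(body, function(f) trimws(f[1L]), "")
  if (anyDuplicated(sampleIds))
    stop("duplicate sample IDs in header: ",
         paste(unique(sampleIds[duplicated(sampleIds)]), collapse = ", "))
  if (anyDuplicated(geneIds))
    stop("duplicate gene IDs: ",
         paste(unique(geneIds[duplicated(geneIds)]), collapse = ", "))

  cells <- vapply(body, function(f) trimws(f[-1L]), character(ncolBody))
  cells <- if (ncolBody == 1L) matrix(cells, nrow = 1L) else cells
  # cells is ncolBody x nGenes here; parse then transpose
  vals <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(vals) & !(cells %in% c("NA", "nan", "NaN", "")))
  if (length(bad)) {
    i <- bad[1L]
    gene <- geneIds[ceiling(i / ncolBody)]
    smp <- sampleIds[(i - 1L) %% ncolBody + 1L]
    stop("parse error: non-numeric value '", cells[i], "' at gene '", gene,
         "', sample '", smp, "'")
  }
  m <- t(matrix(vals, nrow = ncolBody,
                dimnames = list(sampleIds, geneIds)))
  if (transpose) {
    m <- t(m)
  }

  if (anyNA(m)) {
    if (dropIncomplete) {
      drop <- rownames(m)[apply(m, 1L, anyNA)]
      message("dropping ", length(drop), " gene(s) with missing values")
      m <- m[setdiff(rownames(m), drop), , drop = FALSE]
      if (nrow(m) == 0L) stop("all genes dropped due to missing values")
    } else {
      ij <- which(is.na(m), arr.ind = TRUE)[1L, ]
      stop("missing value at gene '", rownames(m)[ij[1L]], "', sample '",
           colnames(m)[ij[2L]],
           "' (use dropIncomplete = TRUE to drop such genes)")
    }
  }
  if (!all(is.finite(m)))
    stop("non-finite expression values in ", path)

  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(metadata)) {
    md <- if (is.character(metadata)) readSampleMetadata(metadata) else
      S4Vectors::DataFrame(metadata)
    if (is.null(rownames(md))) {
      if (!"sample_id" %in% colnames(md))
        stop("metadata must have a 'sample_id' column")
      rownames(md) <- md$sample_id
    }
    .checkPresent(colnames(m), rownames(md), "sample in metadata")
    cd <- md[colnames(m), setdiff(colnames(md), "sample_id"), drop = FALSE]
  }
  SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = m), colData = cd)
}

#' Write an expression matrix to a delimited text file
#'
#' Inverse of [readExpressionMatrix()]: header row of sample IDs (with a
#' leading `gene_id` field), one row per gene, full printed precision so
#' that a write/read round trip reproduces the values.
#'
#' @param x matrix or SummarizedExperiment.
#' @param path output file path.
#' @param format "auto", "tsv" or "csv" (as in [readExpressionMatrix()]).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  sep <- switch(format,
    auto = if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t",
    tsv = "\t", csv = ",")
  m <- .exprs(x)
  header <- paste(c("gene_id", colnames(m)), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i],
            format(m[i, ], digits = 17, trim = TRUE, scientific = FALSE)),
          collapse = sep), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a gene signature from a plain-text file
#'
#' One gene ID per line; blank lines and `#` comments are ignored.
#' Duplicated IDs are dropped (first occurrence kept) with a warning. When
#' an expression matrix is supplied, the signature is restricted to the IDs
#' present in the matrix; absent IDs are reported in a warning and in the
#' `"absent"` attribute of the result, never silently dropped.
#'
#' @param path path to the signature file.
#' @param expression optional matrix or SummarizedExperiment whose row names
#'   the signature is matched against.
#' @param name signature label (defaults to the file name).
#' @return a [GeneSignature-class]; `attr(result, "absent")` lists IDs not
#'   found in `expression`.
#' @export
readGeneSignature <- function(path, expression = NULL, name = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- sub("#.*$", "", ids)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    warning("duplicated signature IDs dropped (first occurrence kept): ",
            paste(dup, collapse = ", "))
    ids <- ids[!duplicated(ids)]
  }
  absent <- character(0)
  if (!is.null(expression)) {
    have <- rownames(.exprs(expression))
    absent <- setdiff(ids, have)
    if (length(absent)) {
      warning(length(absent), " signature ID(s) absent from the matrix: ",
              paste(absent, collapse = ", "))
      ids <- ids[ids %in% have]
    }
  }
  if (length(ids) < 2L)
    stop("signature too small: fewer than 2 usable gene IDs in ", path)
  sig <- GeneSignature(name %||% basename(path), ids)
  attr(sig, "absent") <- absent
  sig
}

#' Read a sample metadata table
#'
#' Tab-separated table with a `sample_id` column; `group`, `pair_id` and
#' `timepoint` columns are recognised downstream and all optional.
#'
#' @param path path to the TSV file.
#' @return a [S4Vectors::DataFrame] keyed by `sample_id`.
#' @export
readSampleMetadata <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"sample_id" %in% colnames(df))
    stop("metadata must have a 'sample_id' column")
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample IDs in metadata")
  md <- S4Vectors::DataFrame(df)
  rownames(md) <- df$sample_id
  md
}

#' Subset an expression matrix by genes and/or samples
#'
#' The ordering of the result follows the request, not the source matrix,
#' so a reversed gene list yields reversed rows. Unknown IDs are an error
#' naming the offending ID.
#'
#' @param x matrix or SummarizedExperiment.
#' @param genes [GeneSignature-class] or character vector of gene IDs
#'   (NULL keeps all genes).
#' @param samples [SampleGroup-class] or character vector of sample IDs
#'   (NULL keeps all samples).
#' @return an object of the same class as `x`, subset and reordered.
#' @export
subsetExpression <- function(x, genes = NULL, samples = NULL) {
  m <- .exprs(x)
  gi <- if (is.null(genes)) rownames(m) else .geneIdsOf(genes)
  si <- if (is.null(samples)) colnames(m) else .sampleIdsOf(samples)
  .checkPresent(gi, rownames(m), "gene ID")
  .checkPresent(si, colnames(m), "sample ID")
  if (is(x, "SummarizedExperiment")) x[gi, si] else m[gi, si, drop = FALSE]
}

#' Serialise a prototype pair to JSON
#'
#' Fixed keys `signature`, `high`, `low`, `provenance`, so that fitting and
#' classification can run as separate invocations on different cohorts.
#'
#' @param prototypes a [PrototypePair-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePrototypes <- function(prototypes, path) {
  stopifnot(is(prototypes, "PrototypePair"))
  doc <- list(signature = prototypes@signature@geneIds,
              signature_name = prototypes@signature@name,
              high = prototypes@high,
              low = prototypes@low,
              provenance = prototypes@provenance)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a prototype pair from JSON
#'
#' @param path path to a file written by [writePrototypes()].
#' @return a [PrototypePair-class].
#' @export
readPrototypes <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (k in c("signature", "high", "low"))
    if (is.null(doc[[k]])) stop("prototype file missing key '", k, "'")
  new("PrototypePair",
      signature = GeneSignature(doc$signature_name %||% "signature",
                                doc$signature),
      high = as.numeric(doc$high), low = as.numeric(doc$low),
      provenance = as.list(doc$provenance))
}
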