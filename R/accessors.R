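## Constructors, accessors and show methods for the data containers.

#' Build an AlleleCountTable
#'
#' @param ranges GRanges of width-1 SNP positions.
#' @param counts 4-d array `sites x types x bulks x conditions`, dimnames on
#'   dimensions 2-4.
#' @param metadata optional provenance list.
#' @return an [AlleleCountTable-class] object.
#' @export
AlleleCountTable <- function(ranges, counts, metadata = list()) {
  storage.mode(counts) <- "integer"
  new("AlleleCountTable", rowRanges = ranges, counts = counts,
      metadata = metadata)
}

#' @describeIn AlleleCountTable site coordinates as a GRanges.
#' @param x an AlleleCountTable.
#' @export
siteRanges <- function(x) x@rowRanges

#' @describeIn AlleleCountTable the raw count array.
#' @export
alleleCounts <- function(x) x@counts

#' @describeIn AlleleCountTable SNP-type (base) dimension names.
#' @export
typeNames <- function(x) dimnames(x@counts)[[2L]]

#' @describeIn AlleleCountTable bulk dimension names.
#' @export
bulkNames <- function(x) dimnames(x@counts)[[3L]]

#' @describeIn AlleleCountTable condition dimension names.
#' @export
conditionNames <- function(x) dimnames(x@counts)[[4L]]

#' @describeIn AlleleCountTable provenance metadata list.
#' @export
tableMetadata <- function(x) x@metadata

#' Pool counts across bulks and (optionally) conditions
#'
#' Returns the site-by-type matrix of counts summed over the four
#' bulk-condition cells, or over the bulks of a single condition.  This is
#' the pooled total the site-validation thresholds refer to.
#'
#' @param x an AlleleCountTable.
#' @param condition a condition name, or `NULL` to pool everything.
#' @return integer matrix, sites in rows, SNP-types in columns.
#' @export
pooledCounts <- function(x, condition = NULL) {
  cnt <- x@counts
  if (!is.null(condition)) {
    if (!condition %in% conditionNames(x))
      stop("unknown condition: ", condition)
    cnt <- cnt[, , , condition, drop = FALSE]
  }
  out <- apply(cnt, c(1L, 2L), sum)
  dimnames(out) <- list(NULL, typeNames(x))
  out
}

setMethod("length", "AlleleCountTable", function(x) length(x@rowRanges))

setMethod("[", "AlleleCountTable", function(x, i, j, ..., drop = FALSE) {
  AlleleCountTable(x@rowRanges[i], x@counts[i, , , , drop = FALSE],
                   metadata = x@metadata)
})

setMethod("show", "AlleleCountTable", function(object) {
  cat(sprintf("AlleleCountTable: %d sites x %d types x %d bulks x %d conditions\n",
              length(object), length(typeNames(object)),
              length(bulkNames(object)), length(conditionNames(object))))
  cat("  types:", paste(typeNames(object), collapse = ", "), "\n")
  cat("  bulks:", paste(bulkNames(object), collapse = ", "), "\n")
  cat("  conditions:", paste(conditionNames(object), collapse = ", "), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

#' Build an ExpressionMatrix
#'
#' @param counts integer gene-by-sample matrix with row and column names.
#' @param geneLength per-gene lengths in bp.
#' @param librarySize per-sample library sizes in reads; defaults to the
#'   column sums of `counts`.
#' @param colData optional extra per-sample annotation (a DataFrame or
#'   data.frame); `library_size` is added/overwritten.
#' @return an [ExpressionMatrix-class].
#' @export
ExpressionMatrix <- function(counts, geneLength, librarySize = NULL,
                             colData = NULL) {
  counts <- as.matrix(counts)
  if (is.null(librarySize)) librarySize <- colSums(counts)
  if (is.null(colData)) {
    colData <- DataFrame(row.names = colnames(counts))
  } else {
    colData <- DataFrame(colData, row.names = colnames(counts))
  }
  colData$library_size <- as.numeric(librarySize)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(gene_length = as.numeric(geneLength),
                        row.names = rownames(counts)),
    colData = colData)
  new("ExpressionMatrix", se)
}

#' @describeIn ExpressionMatrix per-gene lengths in bp.
#' @param x an ExpressionMatrix.
#' @export
geneLengths <- function(x) SummarizedExperiment::rowData(x)$gene_length

#' @describeIn ExpressionMatrix per-sample library sizes in reads.
#' @export
librarySizes <- function(x) {
  stats::setNames(SummarizedExperiment::colData(x)$library_size, colnames(x))
}

#' @describeIn ExpressionMatrix the counts assay.
#' @export
exprCounts <- function(x) SummarizedExperiment::assay(x, "counts")

setMethod("show", "PanelTruth", function(object) {
  cat(sprintf("PanelTruth: %d SNPs; %d tolerant + %d sensitive lines\n",
              length(object@sites), nrow(object@genoTolerant),
              nrow(object@genoSensitive)))
  cat(sprintf("  causal locus: %s:%d; %d truly linked SNPs\n",
              as.character(seqnames(object@causal)), start(object@causal),
              sum(mcols(object@sites)$linked)))
})

#' @describeIn PanelTruth SNP coordinates with truth annotation.
#' @param x a PanelTruth.
#' @export
truthSites <- function(x) x@sites

#' @describeIn PanelTruth the causal locus as a length-1 GRanges.
#' @export
causalLocus <- function(x) x@causal

setMethod("show", "DegTable", function(object) {
  md <- metadata(object)
  cat(sprintf("DegTable: %s vs %s; %d genes tested, %d significant\n",
              md$side_a %||% "A", md$side_b %||% "B",
              nrow(object), sum(object$significant)))
  callNextMethod()
})

`%||%` <- function(a, b) if (is.null(a)) b else a
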