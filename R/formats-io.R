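## External formats.  Internally coordinates are carried by GRanges (1-based
## inclusive, as in GFF3/VCF); converters touch coordinates only at the
## boundary with flat files.

#' Read a per-site allele-depth table
#'
#' Two dialects are supported.  The canonical `tsv` interchange is a long
#' table with header columns `chrom`, `pos`, `bulk`, `condition` and one
#' column per observed SNP-type (base), one row per site-bulk-condition
#' cell.  The `vcf` dialect reads per-sample allelic depths (`AD`) from a
#' VCF whose samples are named `bulk_condition` (e.g. `tolerant_normal`);
#' only biallelic SNVs are used and only the AD field is consulted.
#'
#' Cells absent from the input are recorded as zero; their number is kept
#' in the load summary (`tableMetadata(x)$missing_cells`) and reported with
#' a warning.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return an [AlleleCountTable-class].
#' @export
readAlleleCounts <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "tsv") .readAlleleCountsTsv(path) else .readAlleleCountsVcf(path)
}

.readAlleleCountsTsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop("malformed allele-count table '", path, "': ",
                             conditionMessage(e)))
  need <- c("chrom", "pos", "bulk", "condition")
  if (!all(need %in% colnames(df)))
    stop("allele-count TSV needs columns ",
         paste(need, collapse = ", "))
  typeCols <- setdiff(colnames(df), need)
  if (!length(typeCols)) stop("no SNP-type columns found")
  for (tc in typeCols) {
    bad <- which(is.na(df[[tc]]) | df[[tc]] < 0 |
                   df[[tc]] != round(df[[tc]]))
    if (length(bad))
      stop(sprintf("parse error at line %d: column '%s' must be a %s",
                   bad[1L] + 1L, tc, "non-negative integer count"))
  }
  keyCell <- paste(df$chrom, df$pos, df$bulk, df$condition, sep = "\r")
  if (anyDuplicated(keyCell)) {
    d <- which(duplicated(keyCell))[1L]
    stop(sprintf("duplicate record at line %d: (%s, %s, %s, %s)",
                 d + 1L, df$chrom[d], df$pos[d], df$bulk[d], df$condition[d]))
  }
  siteKey <- unique(df[, c("chrom", "pos")])
  siteKey <- siteKey[order(siteKey$chrom, siteKey$pos), , drop = FALSE]
  bulks <- sort(unique(df$bulk))
  conds <- sort(unique(df$condition))
  cnt <- array(0L, dim = c(nrow(siteKey), length(typeCols), length(bulks),
                           length(conds)),
               dimnames = list(NULL, typeCols, bulks, conds))
  si <- match(paste(df$chrom, df$pos), paste(siteKey$chrom, siteKey$pos))
  bi <- match(df$bulk, bulks)
  ci <- match(df$condition, conds)
  for (t in seq_along(typeCols))
    cnt[cbind(si, t, bi, ci)] <- as.integer(df[[typeCols[t]]])
  nMissing <- nrow(siteKey) * length(bulks) * length(conds) - nrow(df)
  if (nMissing > 0)
    warning(nMissing, " missing site/bulk/condition cells recorded as zero")
  gr <- GRanges(siteKey$chrom, IRanges(siteKey$pos, width = 1L))
  AlleleCountTable(gr, cnt, metadata = list(missing_cells = nMissing,
                                            source = path))
}

.readAlleleCountsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD (allelic depth) field")
  ref <- as.character(VariantAnnotation::ref(vcf))
  altL <- VariantAnnotation::alt(vcf)
  keep <- lengths(altL) == 1L & nchar(ref) == 1L &
    nchar(as.character(unlist(altL))) == 1L
  if (!all(keep)) {
    warning(sum(!keep), " non-biallelic or non-SNV records dropped")
    vcf <- vcf[keep]
    ad <- ad[keep, , drop = FALSE]
    ref <- ref[keep]
    altL <- altL[keep]
  }
  alt <- as.character(unlist(altL))
  samples <- colnames(ad)
  bulks <- sub("_.*$", "", samples)
  conds <- sub("^[^_]+_", "", samples)
  ub <- sort(unique(bulks)); uc <- sort(unique(conds))
  bases <- c("A", "C", "G", "T")
  gr <- granges(SummarizedExperiment::rowRanges(vcf))
  mcols(gr) <- NULL
  names(gr) <- NULL
  cnt <- array(0L, dim = c(length(gr), 4L, length(ub), length(uc)),
               dimnames = list(NULL, bases, ub, uc))
  for (s in seq_along(samples)) {
    depths <- ad[, s]
    refd <- vapply(depths, function(v) as.integer(v[1L]), integer(1))
    altd <- vapply(depths, function(v) as.integer(v[2L]), integer(1))
    refd[is.na(refd)] <- 0L; altd[is.na(altd)] <- 0L
    bi <- match(bulks[s], ub); ci <- match(conds[s], uc)
    cnt[cbind(seq_along(gr), match(ref, bases), bi, ci)] <-
      cnt[cbind(seq_along(gr), match(ref, bases), bi, ci)] + refd
    cnt[cbind(seq_along(gr), match(alt, bases), bi, ci)] <-
      cnt[cbind(seq_along(gr), match(alt, bases), bi, ci)] + altd
  }
  o <- order(as.character(seqnames(gr)), start(gr))
  AlleleCountTable(gr[o], cnt[o, , , , drop = FALSE],
                   metadata = list(missing_cells = 0L, source = path))
}

#' Write an allele-count table in the canonical TSV dialect
#'
#' One row per site-bulk-condition cell, deterministic row and column
#' order; [readAlleleCounts()] restores the counts exactly.
#'
#' @param x an AlleleCountTable.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeAlleleCounts <- function(x, path) {
  gr <- siteRanges(x)
  bulks <- bulkNames(x); conds <- conditionNames(x); types <- typeNames(x)
  rows <- expand.grid(site = seq_along(gr), bulk = bulks, condition = conds,
                      stringsAsFactors = FALSE)
  rows <- rows[order(rows$site, rows$bulk, rows$condition), , drop = FALSE]
  out <- data.frame(chrom = as.character(seqnames(gr))[rows$site],
                    pos = start(gr)[rows$site],
                    bulk = rows$bulk, condition = rows$condition,
                    stringsAsFactors = FALSE)
  for (t in types)
    out[[t]] <- x@counts[cbind(rows$site, match(t, types),
                               match(rows$bulk, bulks),
                               match(rows$condition, conds))]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Keeps `gene`-typed features; coordinates stay 1-based inclusive as in
#' the file.  The gene identifier is taken from `ID` (falling back on
#' `gene_id`/`Name`).
#'
#' @param path GFF3 file.
#' @return GRanges with an mcol `gene_id` (strand preserved but ignored by
#'   SNP assignment).
#' @export
readGeneModels <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) stop("malformed GFF3 '", path, "': ",
                                          conditionMessage(e)))
  if (length(gr) == 0L)
    return(GRanges(gene_id = character(0)))
  if (!is.null(gr$type)) gr <- gr[gr$type == "gene"]
  id <- gr$ID %||% gr$gene_id %||% gr$Name
  if (is.null(id) || anyNA(id) || any(id == ""))
    stop("gene feature without an identifier in ", path)
  if (anyDuplicated(id)) stop("duplicated gene identifiers in ", path)
  mcols(gr) <- DataFrame(gene_id = as.character(id))
  gr
}

#' Write gene models as GFF3
#'
#' @param genes GRanges with `gene_id` mcol.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneModels <- function(genes, path) {
  out <- genes
  mcols(out) <- DataFrame(source = "bsrseq", type = "gene",
                          ID = genes$gene_id)
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

#' Read a gene-by-sample count matrix
#'
#' Expects a TSV with a `gene_id` first column, an optional `length` column
#' (gene length in bp) and one integer column per sample.  Library sizes
#' default to column sums; a two-column sidecar TSV (`sample`,
#' `library_size`) overrides them.
#'
#' @param path count matrix TSV.
#' @param geneLength per-gene lengths, used when the file has no `length`
#'   column.
#' @param librarySizePath optional sidecar TSV with explicit library sizes.
#' @return an [ExpressionMatrix-class].
#' @export
readCountMatrix <- function(path, geneLength = NULL, librarySizePath = NULL) {
  nf <- utils::count.fields(path, sep = "\t")
  if (length(unique(nf)) != 1L)
    stop("ragged count matrix: rows have ", paste(unique(nf), collapse = "/"),
         " fields")
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop("first column must be 'gene_id'")
  if (anyDuplicated(df$gene_id))
    stop("duplicated gene id: ", df$gene_id[duplicated(df$gene_id)][1L])
  if ("length" %in% colnames(df)) {
    geneLength <- df$length
    df$length <- NULL
  }
  if (is.null(geneLength)) stop("gene lengths missing (no 'length' column)")
  sampleCols <- setdiff(colnames(df), "gene_id")
  cnt <- as.matrix(df[, sampleCols, drop = FALSE])
  if (anyNA(cnt) || any(cnt != round(cnt)) || any(cnt < 0))
    stop("counts must be non-negative integers")
  storage.mode(cnt) <- "integer"
  rownames(cnt) <- df$gene_id
  libSize <- colSums(cnt)
  if (!is.null(librarySizePath)) {
    ls <- utils::read.delim(librarySizePath, stringsAsFactors = FALSE)
    if (!all(c("sample", "library_size") %in% colnames(ls)))
      stop("library-size sidecar needs 'sample' and 'library_size' columns")
    m <- match(colnames(cnt), ls$sample)
    if (anyNA(m)) stop("library sizes missing for some samples")
    libSize <- ls$library_size[m]
  }
  ExpressionMatrix(cnt, geneLength = geneLength, librarySize = libSize)
}

#' Write a count matrix (with gene lengths) as TSV
#'
#' @param x an ExpressionMatrix.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path) {
  out <- data.frame(gene_id = rownames(x), length = geneLengths(x),
                    exprCounts(x), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
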