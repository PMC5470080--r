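test_that("allele-count TSV parses to per-cell counts with correct totals", {
  df <- data.frame(chrom = c("chr1", "chr2"), pos = c(100L, 250L),
                   bulk = "tolerant", condition = "normal",
                   A = c(10L, 0L), C = 0L, G = c(5L, 7L), T = c(0L, 3L))
  act <- makeAct(df)
  expect_s4_class(act, "AlleleCountTable")
  expect_equal(length(act), 2L)
  pooled <- pooledCounts(act)
  expect_equal(unname(rowSums(pooled)), c(15, 10))
  expect_equal(unname(pooled[1, "A"]), 10L)
  expect_equal(unname(pooled[2, "G"]), 7L)
})

test_that("malformed and duplicated allele-count rows are rejected by line", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tbulk\tcondition\tA\tG",
               "chr1\t100\ttolerant\tnormal\t-3\t5"), f)
  expect_error(readAlleleCounts(f), "line 2")
  writeLines(c("chrom\tpos\tbulk\tcondition\tA\tG",
               "chr1\t100\ttolerant\tnormal\t3\t5",
               "chr1\t100\ttolerant\tnormal\t1\t1"), f)
  expect_error(readAlleleCounts(f), "duplicate")
})

test_that("missing cells load as zero and are counted in the load summary", {
  df <- data.frame(chrom = "chr1", pos = c(100L, 100L, 200L),
                   bulk = c("tolerant", "sensitive", "tolerant"),
                   condition = "normal", A = 5L, C = 0L, G = 5L, T = 0L)
  expect_warning(act <- makeActRaw(df), "missing")
  expect_equal(tableMetadata(act)$missing_cells, 1L)
  expect_equal(sum(alleleCounts(act)[2, , "sensitive", "normal"]), 0)
})

test_that("allele counts round-trip through the TSV writer exactly", {
  cfg <- simulationConfig(n_snps = 40L, seed = 5L)
  truth <- simulatePanel(cfg)
  act <- simulateAlleleCounts(truth, cfg, "normal", seed = 6L)
  f <- tempfile(fileext = ".tsv")
  writeAlleleCounts(act, f)
  back <- readAlleleCounts(f)
  expect_equal(as.character(seqnames(siteRanges(back))),
               as.character(seqnames(siteRanges(act))))
  expect_equal(start(siteRanges(back)), start(siteRanges(act)))
  ## counts identical cell by cell (dimension order may be normalised)
  expect_equal(
    alleleCounts(back)[, typeNames(act), bulkNames(act),
                       conditionNames(act), drop = FALSE],
    alleleCounts(act), ignore_attr = TRUE)
})

test_that("VCF allelic depths map to bulk-condition cells", {
  txt <- c("##fileformat=VCFv4.2",
           paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                  "Description=\"Allelic depths\">"),
           "##contig=<ID=chr1>",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "tolerant_normal", "sensitive_normal",
                 sep = "\t"),
           paste("chr1", "100", ".", "A", "G", ".", "PASS", ".", "AD",
                 "12,8", "5,15", sep = "\t"),
           paste("chr1", "200", ".", "C", "T", ".", "PASS", ".", "AD",
                 "3,4", "6,7", sep = "\t"))
  f <- tempfile(fileext = ".vcf")
  writeLines(txt, f)
  act <- readAlleleCounts(f, dialect = "vcf")
  expect_equal(length(act), 2L)
  cell <- alleleCounts(act)[1, , "tolerant", "normal"]
  expect_equal(unname(cell[c("A", "G")]), c(12L, 8L))
  expect_equal(unname(alleleCounts(act)[2, c("C", "T"), "sensitive",
                                        "normal"]), c(6L, 7L))
})

test_that("GFF3 gene models preserve 1-based inclusive spans and strand", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=geneA",
               "chr2\tsrc\tgene\t50\t80\t.\t-\t.\tID=geneB"), f)
  gm <- readGeneModels(f)
  expect_equal(gm$gene_id, c("geneA", "geneB"))
  expect_equal(start(gm), c(1000L, 50L))
  expect_equal(end(gm), c(2000L, 80L))
  expect_equal(as.character(strand(gm)), c("+", "-"))
  ## round-trip
  f2 <- tempfile(fileext = ".gff3")
  writeGeneModels(gm, f2)
  back <- readGeneModels(f2)
  expect_equal(start(back), start(gm))
  expect_equal(end(back), end(gm))
  expect_equal(as.character(strand(back)), as.character(strand(gm)))
})

test_that("empty and malformed GFF3 behave as specified", {
  f <- tempfile(fileext = ".gff3")
  writeLines("##gff-version 3", f)
  expect_equal(length(readGeneModels(f)), 0L)
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t2000\t1000\t.\t+\t.\tID=geneA"), f)
  expect_error(readGeneModels(f), "malformed")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tfoo=bar"), f)
  expect_error(readGeneModels(f), "identifier")
})

test_that("count matrices load with column-sum or sidecar library sizes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength\ts1\ts2",
               "g1\t1000\t10\t20",
               "g2\t2000\t0\t5",
               "g3\t500\t7\t1"), f)
  em <- readCountMatrix(f)
  expect_s4_class(em, "ExpressionMatrix")
  expect_equal(unname(librarySizes(em)), c(17, 26))
  expect_equal(geneLengths(em), c(1000, 2000, 500))
  side <- tempfile(fileext = ".tsv")
  writeLines(c("sample\tlibrary_size", "s1\t100", "s2\t200"), side)
  em2 <- readCountMatrix(f, librarySizePath = side)
  expect_equal(unname(librarySizes(em2)), c(100, 200))
})

test_that("ragged, non-integer and duplicated count rows are format errors", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tlength\ts1\ts2", "g1\t1000\t10"), f)
  expect_error(readCountMatrix(f), "ragged")
  writeLines(c("gene_id\tlength\ts1\ts2", "g1\t1000\t1.5\t2"), f)
  expect_error(readCountMatrix(f), "integer")
  writeLines(c("gene_id\tlength\ts1\ts2", "g1\t1000\t1\t2",
               "g1\t900\t3\t4"), f)
  expect_error(readCountMatrix(f), "duplicated")
})

test_that("expression matrices round-trip through the TSV writer", {
  ex <- simulateExpression(simulationConfig(n_genes = 20L, n_de_genes = 2L),
                           seed = 3L)
  f <- tempfile(fileext = ".tsv")
  writeCountMatrix(ex$matrix, f)
  back <- readCountMatrix(f)
  expect_equal(exprCounts(back), exprCounts(ex$matrix))
  expect_equal(geneLengths(back), geneLengths(ex$matrix))
})
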