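## In-code fixtures shared across the suite.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(S4Vectors)
})

## AlleleCountTable from a long data.frame (chrom, pos, bulk, condition,
## one column per base)
makeAct <- function(df, types = c("A", "C", "G", "T")) {
  f <- tempfile(fileext = ".tsv")
  for (t in types) if (is.null(df[[t]])) df[[t]] <- 0L
  df <- df[, c("chrom", "pos", "bulk", "condition", types)]
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  suppressWarnings(readAlleleCounts(f))
}

## like makeAct but letting load warnings through
makeActRaw <- function(df, types = c("A", "C", "G", "T")) {
  f <- tempfile(fileext = ".tsv")
  for (t in types) if (is.null(df[[t]])) df[[t]] <- 0L
  df <- df[, c("chrom", "pos", "bulk", "condition", types)]
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  readAlleleCounts(f)
}

## four-cell (2 bulks x 2 conditions) table with identical counts per cell
makeUniformAct <- function(chrom, pos, perCell) {
  chrom <- rep_len(chrom, length(pos))
  grid <- expand.grid(bulk = c("tolerant", "sensitive"),
                      condition = c("normal", "waterlogged"),
                      site = seq_along(pos), stringsAsFactors = FALSE)
  df <- data.frame(chrom = chrom[grid$site], pos = pos[grid$site],
                   bulk = grid$bulk, condition = grid$condition)
  for (b in c("A", "C", "G", "T"))
    df[[b]] <- vapply(grid$site, function(i) perCell[[i]][[b]] %||% 0L,
                      numeric(1))
  makeAct(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## a PanelTruth with prescribed bulk allele frequencies (one chromosome)
makeTruth <- function(fT, fS, mT = 8L, mS = 10L) {
  n <- length(fT)
  gr <- GRanges("chr1", IRanges(seq_len(n) * 1000L, width = 1L))
  mcols(gr) <- DataFrame(coupling = rep(NA_real_, n), f_tolerant = fT,
                         f_sensitive = fS, linked = rep(FALSE, n),
                         allele_a = rep("A", n), allele_b = rep("G", n))
  genoT <- matrix(FALSE, mT, n)
  for (i in seq_len(n)) genoT[seq_len(round(fT[i] * mT)), i] <- TRUE
  genoS <- matrix(FALSE, mS, n)
  for (i in seq_len(n)) genoS[seq_len(round(fS[i] * mS)), i] <- TRUE
  new("PanelTruth", sites = gr, genoTolerant = genoT, genoSensitive = genoS,
      causal = GRanges("chr1", IRanges(1000L, width = 1L)),
      config = simulationConfig())
}

## GRanges of linkage-scan shape from plain vectors
makeScan <- function(chrom, pos, posterior, allele_a = "A", allele_b = "G") {
  gr <- GRanges(chrom, IRanges(pos, width = 1L))
  mcols(gr) <- DataFrame(allele_a = rep_len(allele_a, length(gr)),
                         allele_b = rep_len(allele_b, length(gr)),
                         posterior = posterior)
  gr
}

## write a FASTQ from sequences and integer phred vectors
writeFastq <- function(path, seqs, quals, offset = 33L) {
  stopifnot(length(seqs) == length(quals))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(c(sprintf("@read%d", i), seqs[i], "+",
                 rawToChar(as.raw(quals[[i]] + offset))), con)
  }
  invisible(path)
}

## gene models from compact vectors
makeGenes <- function(gene_id, chrom, start, end, strand = "*") {
  gr <- GRanges(chrom, IRanges(start, end),
                strand = rep_len(strand, length(start)))
  mcols(gr) <- DataFrame(gene_id = gene_id)
  gr
}
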