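#' Numeric read-quality filter for FASTQ
#'
#' Discards a read when the fraction of unknown (N) bases exceeds
#' `cfg@max_n_fraction`, or when the fraction of bases with a phred score at
#' or below `cfg@low_quality_phred` exceeds `cfg@max_low_quality_fraction`
#' (defaults: 5%, Q10, 20%).  Kept reads are written unchanged.  A read
#' failing both rules is counted once, under the N rule, so the summary
#' partitions the input.
#'
#' @param inPath input FASTQ (Sanger/phred+33 by default).
#' @param outPath output FASTQ of kept reads.
#' @param cfg a [readQcConfig()].
#' @param qualityOffset 33 (Sanger) or 64 (old Illumina).
#' @return named integer vector: `input`, `kept`, `discarded_n`,
#'   `discarded_quality`.
#' @export
filterFastq <- function(inPath, outPath, cfg = readQcConfig(),
                        qualityOffset = 33) {
  if (!qualityOffset %in% c(33, 64))
    stop("qualityOffset must be 33 or 64")
  scoring <- if (qualityOffset == 33) "phred" else "illumina"
  .validateFastqRecords(inPath)
  parsed <- tryCatch({
    ## the reader's "metadata columns dropped" note is cosmetic
    r <- suppressWarnings(
      Biostrings::readQualityScaledDNAStringSet(inPath,
                                                quality.scoring = scoring))
    list(reads = r, quals = methods::as(Biostrings::quality(r),
                                        "IntegerList"))
  }, error = function(e) stop("malformed FASTQ '", inPath, "': ",
                              conditionMessage(e)))
  reads <- parsed$reads
  n <- length(reads)
  if (n == 0L) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(), outPath,
                                format = "fastq")
    return(c(input = 0L, kept = 0L, discarded_n = 0L, discarded_quality = 0L))
  }
  w <- Biostrings::width(reads)
  nFrac <- as.vector(Biostrings::letterFrequency(reads, "N")) / w
  lowFrac <- sum(parsed$quals <= cfg@low_quality_phred) / w
  badN <- nFrac > cfg@max_n_fraction
  badQ <- !badN & lowFrac > cfg@max_low_quality_fraction
  kept <- reads[!(badN | badQ)]
  ## Biostrings warns that the quality mcols are dropped from the plain
  ## DNAStringSet; the qualities are passed explicitly, so nothing is lost
  suppressWarnings(
    Biostrings::writeXStringSet(methods::as(kept, "DNAStringSet"), outPath,
                                format = "fastq",
                                qualities = Biostrings::quality(kept)))
  c(input = n, kept = length(kept),
    discarded_n = sum(badN), discarded_quality = sum(badQ))
}

## Structural check on 4-line FASTQ records.  The parser pads a short
## quality string silently, so the sequence/quality length comparison has
## to happen on the raw records.
.validateFastqRecords <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L)
    stop("malformed FASTQ '", path, "': truncated record")
  if (!length(lines)) return(invisible(TRUE))
  seqLen <- nchar(lines[seq(2L, length(lines), by = 4L)])
  qualLen <- nchar(lines[seq(4L, length(lines), by = 4L)])
  bad <- which(seqLen != qualLen)
  if (length(bad))
    stop("malformed FASTQ '", path, "': sequence/quality length mismatch ",
         "in record ", bad[1L])
  invisible(TRUE)
}
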