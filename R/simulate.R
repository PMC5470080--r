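## Synthetic two-bulk generator.  The panel is a set of unrelated inbred
## lines, not an F2: allele-state coupling to the causal locus is modelled
## with an exponential LD-style decay, c(d) = 0.5 + 0.5 exp(-d / L) on the
## causal chromosome and c = 0.5 elsewhere.  Bulk allele frequencies are
## carrier fractions and therefore live on the lattice k/m for a bulk of m
## lines.  Both conditions reuse the same genotypes (expression, not
## genotype, responds to the treatment); only sequencing noise differs
## between conditions.

#' Simulate a two-bulk inbred panel with a single causal locus
#'
#' SNP positions are drawn uniformly per chromosome (weighted by length);
#' the causal site itself is always included as a SNP.  Every tolerant
#' line carries the tolerant allele at the causal locus and every
#' sensitive line the alternative; at a SNP with coupling `c`, a tolerant
#' line carries the causal-coupled allele with probability `c` and a
#' sensitive line with probability `1 - c`.
#'
#' @param cfg a [simulationConfig()]; `cfg@seed` (when not `NA`) makes the
#'   panel deterministic.
#' @return a [PanelTruth-class].
#' @export
simulatePanel <- function(cfg = simulationConfig()) {
  if (!is.na(cfg@seed)) set.seed(cfg@seed)
  chroms <- names(cfg@chromosomes)
  lens <- cfg@chromosomes
  n <- cfg@n_snps
  snpChrom <- sample(chroms, n - 1L, replace = TRUE, prob = lens)
  snpPos <- floor(stats::runif(n - 1L) * lens[snpChrom]) + 1
  snpChrom <- c(cfg@causal_chrom, snpChrom)
  snpPos <- c(cfg@causal_pos, snpPos)
  o <- order(snpChrom, snpPos)
  snpChrom <- snpChrom[o]; snpPos <- snpPos[o]
  d <- ifelse(snpChrom == cfg@causal_chrom,
              abs(snpPos - cfg@causal_pos), Inf)
  coupling <- 0.5 + 0.5 * exp(-d / cfg@ld_decay_length)
  mT <- cfg@n_tolerant_lines; mS <- cfg@n_sensitive_lines
  ## carrier indicator of the tolerant-coupled allele
  genoT <- matrix(stats::runif(mT * n) < rep(coupling, each = mT),
                  nrow = mT, ncol = n)
  genoS <- matrix(stats::runif(mS * n) < rep(1 - coupling, each = mS),
                  nrow = mS, ncol = n)
  bases <- c("A", "C", "G", "T")
  alleleA <- sample(bases, n, replace = TRUE)
  alleleB <- vapply(alleleA,
                    function(b) sample(setdiff(bases, b), 1L), character(1))
  gr <- GRanges(snpChrom, IRanges(snpPos, width = 1L))
  GenomeInfoDb::seqlevels(gr) <- chroms
  mcols(gr) <- DataFrame(coupling = coupling,
                         f_tolerant = colMeans(genoT),
                         f_sensitive = colMeans(genoS),
                         linked = coupling >= cfg@linked_coupling,
                         allele_a = alleleA, allele_b = unname(alleleB))
  new("PanelTruth", sites = gr, genoTolerant = genoT, genoSensitive = genoS,
      causal = GRanges(cfg@causal_chrom,
                       IRanges(cfg@causal_pos, width = 1L)),
      config = cfg)
}

#' Simulate per-site allele depths for one condition
#'
#' Per bulk and site, sequencing depth is Poisson(`mean_depth`); reads of
#' the focal (tolerant-coupled) allele are binomial with success
#' probability `f (1 - e) + (1 - f) e` where `f` is the bulk's true
#' carrier fraction and `e` the base-error rate, so base errors flip reads
#' between the two true alleles symmetrically.  Each remaining
#' (alternative-allele) read is additionally miscalled to one of the two
#' other bases with probability `e/2` apiece, which is what can violate
#' the two-type site rule downstream.
#'
#' @param truth a [PanelTruth-class].
#' @param cfg the [simulationConfig()].
#' @param condition condition label recorded in the table.
#' @param seed optional integer; `NA` continues the ambient RNG stream.
#' @return an [AlleleCountTable-class] with bulks `tolerant`/`sensitive`
#'   and the single condition.
#' @export
simulateAlleleCounts <- function(truth, cfg, condition = "normal",
                                 seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  gr <- truth@sites
  n <- length(gr)
  bases <- c("A", "C", "G", "T")
  eps <- cfg@base_error
  cnt <- array(0L, dim = c(n, 4L, 2L, 1L),
               dimnames = list(NULL, bases, c("tolerant", "sensitive"),
                               condition))
  fs <- list(tolerant = mcols(gr)$f_tolerant,
             sensitive = mcols(gr)$f_sensitive)
  ai <- match(mcols(gr)$allele_a, bases)
  bi <- match(mcols(gr)$allele_b, bases)
  for (b in c("tolerant", "sensitive")) {
    f <- fs[[b]]
    depth <- stats::rpois(n, cfg@mean_depth)
    pf <- f * (1 - eps) + (1 - f) * eps
    nFocal <- stats::rbinom(n, depth, pf)
    m <- depth - nFocal
    nThird1 <- stats::rbinom(n, m, eps / 2)
    nThird2 <- stats::rbinom(n, m - nThird1, (eps / 2) / (1 - eps / 2))
    nAlt <- m - nThird1 - nThird2
    others <- t(vapply(seq_len(n),
                       function(i) setdiff(seq_len(4L), c(ai[i], bi[i])),
                       integer(2)))
    bIdx <- match(b, c("tolerant", "sensitive"))
    cnt[cbind(seq_len(n), ai, bIdx, 1L)] <- nFocal
    cnt[cbind(seq_len(n), bi, bIdx, 1L)] <- nAlt
    cnt[cbind(seq_len(n), others[, 1L], bIdx, 1L)] <- nThird1
    cnt[cbind(seq_len(n), others[, 2L], bIdx, 1L)] <- nThird2
  }
  out <- granges(gr)
  mcols(out) <- NULL
  AlleleCountTable(out, cnt, metadata = list(condition = condition))
}

#' Combine single-condition allele-count tables
#'
#' Binds tables that share sites, types and bulks along the condition
#' dimension.
#'
#' @param ... AlleleCountTable objects with distinct condition names.
#' @return one [AlleleCountTable-class].
#' @export
combineAlleleCounts <- function(...) {
  tabs <- list(...)
  ref <- tabs[[1L]]
  for (t in tabs[-1L]) {
    if (!identical(typeNames(t), typeNames(ref)) ||
        !identical(bulkNames(t), bulkNames(ref)) ||
        length(t) != length(ref))
      stop("tables are not compatible")
  }
  conds <- unlist(lapply(tabs, conditionNames))
  if (anyDuplicated(conds)) stop("duplicated condition names")
  cnt <- array(0L, dim = c(length(ref), length(typeNames(ref)),
                           length(bulkNames(ref)), length(conds)),
               dimnames = list(NULL, typeNames(ref), bulkNames(ref), conds))
  k <- 0L
  for (t in tabs) {
    nc <- length(conditionNames(t))
    cnt[, , , k + seq_len(nc)] <- t@counts
    k <- k + nc
  }
  AlleleCountTable(siteRanges(ref), cnt, metadata = ref@metadata)
}

#' Simulate synthetic gene models
#'
#' Places `cfg@n_genes` genes on the simulated chromosomes (chromosome
#' chosen proportionally to length, start uniform, length uniform in
#' 500-5000 bp).  The first gene is always centred on the causal locus so
#' the causal SNP is genic.
#'
#' @param cfg a [simulationConfig()].
#' @param seed optional integer seed; `NA` continues the ambient stream.
#' @return GRanges with `gene_id` mcols (`gene0001` is the causal gene).
#' @export
simulateGeneModels <- function(cfg = simulationConfig(), seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  n <- cfg@n_genes
  chroms <- names(cfg@chromosomes)
  lens <- cfg@chromosomes
  gChrom <- sample(chroms, n, replace = TRUE, prob = lens)
  gLen <- floor(stats::runif(n, 500, 5001))
  gStart <- floor(stats::runif(n) * pmax(lens[gChrom] - gLen, 1)) + 1
  gChrom[1L] <- cfg@causal_chrom
  gStart[1L] <- max(1, cfg@causal_pos - floor(gLen[1L] / 2))
  gr <- GRanges(gChrom, IRanges(gStart, width = gLen),
                strand = sample(c("+", "-"), n, replace = TRUE))
  GenomeInfoDb::seqlevels(gr) <- chroms
  mcols(gr) <- DataFrame(gene_id = sprintf("gene%04d", seq_len(n)))
  gr
}

## Replicate count draws: NB with var = mu (1 + dispersion * mu); the
## dispersion -> 0 limit is Poisson.
.drawCounts <- function(mu, dispersion) {
  if (dispersion > 0) stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  else stats::rpois(length(mu), mu)
}

#' Simulate replicate expression matrices with planted DE genes
#'
#' Baseline per-replicate expected counts are drawn log-uniformly over
#' three decades (1 to 1000 reads); `cfg@n_de_genes` genes receive a
#' `2^(+/- de_log2fc)` multiplier in the tolerant bulk (both conditions),
#' emulating constitutive pool-divergent expression.  Counts are negative
#' binomial with dispersion `cfg@nb_dispersion`, scaled to per-replicate
#' library sizes (log-normal around `cfg@library_size_mean`).  Gene
#' lengths are uniform in 500-5000 bp unless supplied.
#'
#' @param cfg a [simulationConfig()].
#' @param geneLength optional per-gene lengths (e.g. widths of
#'   [simulateGeneModels()] output, so models and matrix agree).
#' @param seed optional integer; `NA` continues the ambient RNG stream.
#' @return list with `matrix` (an [ExpressionMatrix-class], samples
#'   `bulk_condition_rN`) and `truth` (data.frame `gene_id`, `de`,
#'   `log2fc` -- signed planted effect, tolerant over sensitive).
#' @export
simulateExpression <- function(cfg = simulationConfig(), geneLength = NULL,
                               seed = NA_integer_) {
  if (!is.na(seed)) set.seed(seed)
  n <- cfg@n_genes
  geneIds <- sprintf("gene%04d", seq_len(n))
  if (is.null(geneLength)) geneLength <- floor(stats::runif(n, 500, 5001))
  base <- 10^stats::runif(n, 0, 3)
  deIdx <- if (cfg@n_de_genes > 0) sample(n, cfg@n_de_genes) else integer(0)
  sgn <- sample(c(-1, 1), length(deIdx), replace = TRUE)
  log2fc <- numeric(n)
  log2fc[deIdx] <- sgn * cfg@de_log2fc
  bulks <- c("tolerant", "sensitive")
  conds <- c("normal", "waterlogged")
  reps <- seq_len(cfg@n_replicates)
  design <- expand.grid(rep = reps, condition = conds, bulk = bulks,
                        stringsAsFactors = FALSE)[, 3:1]
  sampleNames <- sprintf("%s_%s_r%d", design$bulk, design$condition,
                         design$rep)
  libFactor <- exp(stats::rnorm(nrow(design), 0, 0.1))
  libSize <- cfg@library_size_mean * libFactor
  meanBase <- base / sum(base) * cfg@library_size_mean  # per-replicate scale
  cnt <- matrix(0L, nrow = n, ncol = nrow(design),
                dimnames = list(geneIds, sampleNames))
  for (j in seq_len(nrow(design))) {
    mult <- if (design$bulk[j] == "tolerant") 2^log2fc else rep(1, n)
    cnt[, j] <- .drawCounts(meanBase * mult * libFactor[j], cfg@nb_dispersion)
  }
  em <- ExpressionMatrix(cnt, geneLength = geneLength,
                         colData = DataFrame(bulk = design$bulk,
                                             condition = design$condition,
                                             replicate = design$rep))
  list(matrix = em,
       truth = data.frame(gene_id = geneIds, de = log2fc != 0,
                          log2fc = log2fc, stringsAsFactors = FALSE))
}

#' Write a full synthetic dataset to disk
#'
#' Emits the truth table, one allele-count TSV per condition, the count
#' matrix and the gene models of a simulated study.
#'
#' @param outdir output directory (created if needed).
#' @param truth a [PanelTruth-class].
#' @param counts named list of single- or multi-condition
#'   AlleleCountTable objects; written as `allele_counts_<name>.tsv`.
#' @param expression result of [simulateExpression()].
#' @param genes GRanges from [simulateGeneModels()].
#' @return named character vector of the files written, invisibly.
#' @export
writeSimulation <- function(outdir, truth, counts, expression, genes) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  gr <- truth@sites
  tt <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   coupling = mcols(gr)$coupling,
                   f_tolerant = mcols(gr)$f_tolerant,
                   f_sensitive = mcols(gr)$f_sensitive,
                   linked = mcols(gr)$linked,
                   allele_a = mcols(gr)$allele_a,
                   allele_b = mcols(gr)$allele_b)
  f <- file.path(outdir, "truth_snps.tsv")
  utils::write.table(tt, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files["truth"] <- f
  for (nm in names(counts)) {
    f <- file.path(outdir, sprintf("allele_counts_%s.tsv", nm))
    writeAlleleCounts(counts[[nm]], f)
    files[paste0("counts_", nm)] <- f
  }
  f <- file.path(outdir, "count_matrix.tsv")
  writeCountMatrix(expression$matrix, f)
  files["counts_matrix"] <- f
  f <- file.path(outdir, "de_truth.tsv")
  utils::write.table(expression$truth, f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files["de_truth"] <- f
  f <- file.path(outdir, "genes.gff3")
  writeGeneModels(genes, f)
  files["genes"] <- f
  invisible(files)
}
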