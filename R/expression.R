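## Digital gene-expression profiling: RPKM, the Poisson-tag test for two
## pooled libraries, BH FDR control, DEG calling at the two-fold /
## FDR <= 0.001 gates, and fold-change magnitude binning.

#' RPKM normalisation
#'
#' `RPKM(g, s) = 1e9 * C(g, s) / (N(s) * L(g))` with `C` the read count,
#' `N` the sample's library size in reads and `L` the gene length in bp.
#'
#' @param x an [ExpressionMatrix-class].
#' @return numeric matrix of the same shape as the counts.
#' @export
computeRpkm <- function(x) {
  L <- geneLengths(x)
  N <- librarySizes(x)
  if (any(L <= 0)) stop("gene lengths must be positive")
  if (any(N <= 0)) stop("library sizes must be positive")
  1e9 * sweep(exprCounts(x), 2L, N, "/") / L
}

#' Two-library digital-tag test
#'
#' Tests whether tag counts `x` and `y` from libraries of sizes `n1` and
#' `n2` are compatible with one common relative expression level.  Given
#' `x`, the predictive distribution of the second count under the null is
#' `p(y | x) = (n2/n1)^y (x+y)! / (x! y! (1 + n2/n1)^(x+y+1))`, a negative
#' binomial with size `x + 1` and success probability `n1 / (n1 + n2)`;
#' tail probabilities are computed through that identity (log-space,
#' overflow-free).  The two-sided p-value is the doubled smaller of the
#' lower tail `P(Y <= y | x)` and the strict upper tail `P(Y > y | x)`,
#' capped at 1, which makes the test symmetric in its two libraries:
#' `acTest(x, y, n1, n2) = acTest(y, x, n2, n1)`.
#'
#' @param x,y non-negative tag counts (vectorised).
#' @param n1,n2 positive library sizes.
#' @return two-sided p-value(s) in (0, 1].
#' @export
acTest <- function(x, y, n1, n2) {
  if (any(x < 0) || any(y < 0)) stop("tag counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  q <- n1 / (n1 + n2)
  f <- stats::pnbinom(y, size = x + 1, prob = q)                 # P(Y <= y)
  g <- stats::pnbinom(y, size = x + 1, prob = q, lower.tail = FALSE)
  pmin(1, 2 * pmin(f, g))
}

## predictive pmf p(y | x), exposed for the normalisation check
acPredictive <- function(y, x, n1, n2) {
  stats::dnbinom(y, size = x + 1, prob = n1 / (n1 + n2))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR control (via [stats::p.adjust()]), with input
#' validation; stable under permutation of the input order.
#'
#' @param pvals p-values in `[0, 1]`.
#' @return q-values in the input order.
#' @export
bhAdjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

.FOLD_BINS <- c("2-10", "10-100", "100-1000", ">1000")

## (2, 10], (10, 100], (100, 1000], (1000, Inf); NA below 2
foldBin <- function(fc) {
  cut(fc, breaks = c(2, 10, 100, 1000, Inf), labels = .FOLD_BINS,
      right = TRUE)
}

#' Call differentially expressed genes between two sample groups
#'
#' Replicate counts are summed into one pooled library per side
#' (`pool_sum`), genes with zero pooled counts on both sides are excluded
#' from testing, and each remaining gene is tested with [acTest()] on the
#' pooled counts and pooled library sizes, followed by BH adjustment.  The
#' fold change is the ratio of pseudocounted mean RPKMs,
#' `(mean RPKM_A + pc) / (mean RPKM_B + pc)`, reported as a value `>= 1`
#' with the direction carried separately (`"up"` = higher on side A).  A
#' gene is significant when its fold change strictly exceeds
#' `cfg@fold_change_threshold` and its FDR is at most `cfg@fdr_threshold`.
#'
#' @param x an [ExpressionMatrix-class].
#' @param side_a,side_b disjoint, non-empty character vectors of sample
#'   (column) names.
#' @param cfg a [degConfig()].
#' @return a [DegTable-class]; one row per tested gene.
#' @export
callDegs <- function(x, side_a, side_b, cfg = degConfig()) {
  if (!length(side_a) || !length(side_b)) stop("empty sample group")
  if (length(intersect(side_a, side_b))) stop("sample groups must be disjoint")
  if (!all(c(side_a, side_b) %in% colnames(x)))
    stop("unknown sample names")
  cnt <- exprCounts(x)
  ca <- rowSums(cnt[, side_a, drop = FALSE])
  cb <- rowSums(cnt[, side_b, drop = FALSE])
  Na <- sum(librarySizes(x)[side_a])
  Nb <- sum(librarySizes(x)[side_b])
  tested <- (ca + cb) > 0
  rpkm <- computeRpkm(x)
  ra <- rowMeans(rpkm[, side_a, drop = FALSE])
  rb <- rowMeans(rpkm[, side_b, drop = FALSE])
  pc <- cfg@pseudocount_rpkm
  ratio <- (ra + pc) / (rb + pc)
  fc <- pmax(ratio, 1 / ratio)
  direction <- ifelse(ratio >= 1, "up", "down")
  p <- rep(NA_real_, length(ca))
  p[tested] <- acTest(ca[tested], cb[tested], Na, Nb)
  q <- rep(NA_real_, length(ca))
  q[tested] <- bhAdjust(p[tested])
  sig <- tested & fc > cfg@fold_change_threshold & q <= cfg@fdr_threshold
  bin <- foldBin(fc)
  bin[!sig] <- NA
  out <- DataFrame(gene_id = rownames(x), count_a = ca, count_b = cb,
                   lib_a = Na, lib_b = Nb, rpkm_a = ra, rpkm_b = rb,
                   fold_change = fc, direction = direction,
                   pvalue = p, fdr = q, significant = sig, bin = bin)
  out <- out[tested, , drop = FALSE]
  rownames(out) <- NULL
  tab <- new("DegTable", out)
  metadata(tab) <- list(side_a_samples = side_a, side_b_samples = side_b,
                        side_a = attr(side_a, "label") %||% "A",
                        side_b = attr(side_b, "label") %||% "B",
                        n_excluded_zero = sum(!tested), config = cfg)
  tab
}

#' Construct a minimal DEG table from fold changes and directions
#'
#' Convenience constructor for summarisation workflows where only the
#' significant calls' fold changes and directions are known (e.g. when
#' encoding a published bin table); all genes are marked significant.
#'
#' @param gene_id gene identifiers.
#' @param fold_change fold changes, `>= 1`.
#' @param direction `"up"` or `"down"` per gene.
#' @return a [DegTable-class].
#' @export
degTable <- function(gene_id, fold_change, direction) {
  out <- DataFrame(gene_id = gene_id, count_a = NA_real_, count_b = NA_real_,
                   lib_a = NA_real_, lib_b = NA_real_,
                   rpkm_a = NA_real_, rpkm_b = NA_real_,
                   fold_change = fold_change, direction = direction,
                   pvalue = NA_real_, fdr = NA_real_, significant = TRUE,
                   bin = foldBin(fold_change))
  new("DegTable", out)
}

#' Fold-change magnitude summary of significant DEGs
#'
#' Bins the significant genes of a contrast into the magnitude classes
#' (2, 10], (10, 100], (100, 1000] and (1000, Inf), split by direction,
#' with marginal and grand totals.  A fold change of exactly 10 falls in
#' the 2-10 bin (bins are right-closed).
#'
#' @param degs a [DegTable-class].
#' @return list with `bins` (4 x 2 integer matrix, bins x up/down),
#'   `up_total`, `down_total` and `total`.
#' @export
summarizeFoldBins <- function(degs) {
  sig <- degs[degs$significant, , drop = FALSE]
  if (any(sig$fold_change <= 2))
    stop("significant record with fold change <= 2: inconsistent call set")
  bins <- matrix(0L, nrow = 4L, ncol = 2L,
                 dimnames = list(.FOLD_BINS, c("up", "down")))
  tab <- table(foldBin(sig$fold_change),
               factor(sig$direction, levels = c("up", "down")))
  bins[rownames(tab), colnames(tab)] <- tab
  list(bins = bins,
       up_total = sum(bins[, "up"]),
       down_total = sum(bins[, "down"]),
       total = sum(bins))
}

#' Reference DEG fold-change bin counts from a maize waterlogging BSR-seq
#' study
#'
#' Published per-bin counts of significant genes for the four contrasts of
#' a two-pool maize waterlogging experiment (within-pool waterlogged vs
#' untreated for the tolerant and sensitive pools; tolerant vs sensitive
#' under normal and waterlogged conditions).  Shipped as a plain-text
#' fixture; useful as a worked example for [summarizeFoldBins()].
#'
#' @return data.frame with columns `contrast`, `direction`, `bin`, `n`.
#' @export
referenceFoldBinCounts <- function() {
  path <- system.file("extdata", "maize_waterlogging_deg_bins.tsv",
                      package = "bsrseq", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Expand bin counts into a DEG table of representative fold changes
#'
#' Inverse of [summarizeFoldBins()] up to binning: each bin contributes
#' `n` records at a representative fold change inside the bin (5, 50, 500
#' and 2000 for the four classes).
#'
#' @param binCounts data.frame with `direction`, `bin`, `n` (one contrast).
#' @return a [DegTable-class].
#' @export
expandBinCounts <- function(binCounts) {
  rep_fc <- c("2-10" = 5, "10-100" = 50, "100-1000" = 500, ">1000" = 2000)
  if (!all(binCounts$bin %in% names(rep_fc))) stop("unknown bin label")
  fc <- rep(rep_fc[binCounts$bin], binCounts$n)
  dir <- rep(binCounts$direction, binCounts$n)
  degTable(gene_id = sprintf("g%05d", seq_along(fc)), fold_change = fc,
           direction = dir)
}
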