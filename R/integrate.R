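## Candidate-gene integration: cross-contrast DEG overlap with direction
## classes, the SNP-by-DEG candidate table, and marker-interval queries.

#' Overlap two DEG contrasts and classify direction pairs
#'
#' Intersects the significant gene sets of two contrasts over the same
#' gene universe (e.g. tolerant vs sensitive under normal and under
#' waterlogged conditions) and labels each shared gene `concordant`,
#' `opposite_down_then_up` (down in the first contrast, up in the second)
#' or `opposite_up_then_down`.  Genes significant in only one contrast are
#' not part of the overlap.
#'
#' @param deg_a,deg_b [DegTable-class] objects (first and second contrast).
#' @return list with `overlap` (data.frame `gene_id`, `direction_a`,
#'   `direction_b`, `class`) and `class_counts` (named integer vector
#'   partitioning the overlap).
#' @export
overlapDegSets <- function(deg_a, deg_b) {
  sa <- deg_a[deg_a$significant, , drop = FALSE]
  sb <- deg_b[deg_b$significant, , drop = FALSE]
  shared <- sort(intersect(sa$gene_id, sb$gene_id))
  da <- sa$direction[match(shared, sa$gene_id)]
  db <- sb$direction[match(shared, sb$gene_id)]
  cls <- ifelse(da == db, "concordant",
                ifelse(da == "down", "opposite_down_then_up",
                       "opposite_up_then_down"))
  lev <- c("concordant", "opposite_down_then_up", "opposite_up_then_down")
  list(overlap = data.frame(gene_id = shared, direction_a = da,
                            direction_b = db, class = cls,
                            stringsAsFactors = FALSE),
       class_counts = stats::setNames(
         as.integer(table(factor(cls, levels = lev))), lev))
}

#' Build the ranked SNP-by-DEG candidate-gene table
#'
#' Every gene containing at least one SNP of the supplied set (typically
#' the cross-condition overlap of high-probability SNPs) appears exactly
#' once, annotated with its DEG status and direction under each contrast,
#' and ranked by (number of contrasts significant, maximum SNP posterior,
#' SNP count), ties broken by gene id.
#'
#' @param snps GRanges of SNPs with a `posterior` mcol (use
#'   `posterior_a`/`posterior_b` maxima for overlap sets; see Details).
#' @param genes GRanges of gene models with `gene_id`.
#' @param deg_tables named list of [DegTable-class] objects, one per
#'   contrast.
#' @param region optional `list(chrom=, start=, end=)` marker interval; adds
#'   an `in_region` flag (gene span intersects the interval).
#' @return data.frame, one row per SNP-bearing gene, ranked; columns
#'   `gene_id`, `chrom`, `start`, `end`, `n_snps`, `max_posterior`,
#'   `sig_<contrast>` and `dir_<contrast>` per contrast,
#'   `n_contrasts_sig`, and `in_region` when a region is given.
#'
#' @details If `snps` lacks `posterior` but has `posterior_a`/`posterior_b`
#' (an [intersectHighProbability()] overlap), the per-site maximum of the
#' two is used.
#' @export
integrateSnpDeg <- function(snps, genes, deg_tables, region = NULL) {
  post <- mcols(snps)$posterior
  if (is.null(post)) {
    pa <- mcols(snps)$posterior_a; pb <- mcols(snps)$posterior_b
    if (is.null(pa) || is.null(pb))
      stop("snps need a 'posterior' (or 'posterior_a'/'posterior_b') mcol")
    post <- pmax(pa, pb)
  }
  ## disjoint seqlevel sets are a legitimate empty result, not a problem
  hits <- suppressWarnings(findOverlaps(snps, genes, ignore.strand = TRUE))
  if (!length(hits)) {
    out <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), max_posterior = numeric(0),
                      n_contrasts_sig = integer(0))
    return(out)
  }
  gi <- S4Vectors::subjectHits(hits)
  byGene <- split(S4Vectors::queryHits(hits), genes$gene_id[gi])
  geneIdx <- match(names(byGene), genes$gene_id)
  out <- data.frame(
    gene_id = names(byGene),
    chrom = as.character(seqnames(genes))[geneIdx],
    start = start(genes)[geneIdx],
    end = end(genes)[geneIdx],
    n_snps = lengths(byGene),
    max_posterior = vapply(byGene, function(i) max(post[i]), numeric(1)),
    stringsAsFactors = FALSE)
  nSig <- integer(nrow(out))
  for (nm in names(deg_tables)) {
    tab <- deg_tables[[nm]]
    m <- match(out$gene_id, tab$gene_id)
    sig <- !is.na(m) & tab$significant[m]
    out[[paste0("sig_", nm)]] <- sig
    out[[paste0("dir_", nm)]] <- ifelse(sig, tab$direction[m], NA_character_)
    nSig <- nSig + sig
  }
  out$n_contrasts_sig <- nSig
  if (!is.null(region)) {
    inReg <- out$chrom == region$chrom &
      out$start <= region$end & out$end >= region$start
    out$in_region <- inReg
  }
  o <- order(-out$n_contrasts_sig, -out$max_posterior, -out$n_snps,
             out$gene_id)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes intersecting a marker interval
#'
#' Returns the gene models whose 1-based inclusive span intersects
#' `[start, end]` on `chrom` (a single shared base pair counts), sorted by
#' start.  Marker intervals (e.g. between two mapped SSR markers) are
#' supplied as coordinates; no marker database is bundled.
#'
#' @param genes GRanges of gene models with `gene_id`.
#' @param chrom chromosome name.
#' @param start,end interval bounds, `start <= end`.
#' @return GRanges subset, sorted by start.
#' @export
genesInRegion <- function(genes, chrom, start, end) {
  stopifnot(start <= end)
  if (!chrom %in% as.character(GenomeInfoDb::seqlevels(genes)) &&
      !chrom %in% as.character(seqnames(genes))) {
    warning("unknown chromosome: ", chrom)
    return(genes[integer(0)])
  }
  q <- GRanges(chrom, IRanges(start, end))
  hit <- subsetByOverlaps(genes, q, ignore.strand = TRUE)
  hit[order(GenomicRanges::start(hit))]
}
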