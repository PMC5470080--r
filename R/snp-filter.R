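## SNP-site validation.  A valid site carries two and only two supported
## SNP-types: each retained type needs >= min_type_reads reads and
## >= min_type_fraction of the pooled site total, and together the two
## types must hold >= min_two_type_fraction of that total.  Counts are
## pooled across bulks and conditions before typing (the linkage model
## needs the same two alleles in both bulks); per-condition typing is
## available through the `condition` argument of [filterSites()].

#' Classify one SNP site against the two-type validation rules
#'
#' @param counts named vector of pooled read counts per observed SNP-type
#'   (e.g. `c(A = 10, G = 10)`).
#' @param cfg a [snpFilterConfig()].
#' @return list with `pass` (logical), `types` (the two retained SNP-types,
#'   descending count, ties alphabetical; `NULL` unless passing) and
#'   `reason` (`"pass"`, `"monomorphic"`, `"too_many_types"`,
#'   `"low_type_support"` or `"low_combined_fraction"`).
#'
#' @details Failure labels for sites with fewer than two qualifying types
#' are decided by the runner-up type: if the second-largest observed type
#' fails the minimum-read rule the site is `low_type_support` (deeper
#' sequencing could rescue it); if it fails only the fraction rule, or does
#' not exist, the site is `monomorphic`.  Three or more qualifying types is
#' `too_many_types`; two qualifying types below the combined-fraction gate
#' is `low_combined_fraction`.
#' @export
classifySite <- function(counts, cfg = snpFilterConfig()) {
  counts <- counts[counts > 0]
  total <- sum(counts)
  if (total == 0)
    stop("undefined site: no reads at all")
  ord <- order(-counts, names(counts))
  counts <- counts[ord]
  qual <- counts >= cfg@min_type_reads &
    counts / total >= cfg@min_type_fraction
  nq <- sum(qual)
  if (nq == 2L) {
    two <- names(counts)[qual]
    if (sum(counts[qual]) >= cfg@min_two_type_fraction * total)
      return(list(pass = TRUE, types = two, reason = "pass"))
    return(list(pass = FALSE, types = NULL, reason = "low_combined_fraction"))
  }
  if (nq >= 3L)
    return(list(pass = FALSE, types = NULL, reason = "too_many_types"))
  if (length(counts) >= 2L && counts[2L] < cfg@min_type_reads)
    return(list(pass = FALSE, types = NULL, reason = "low_type_support"))
  list(pass = FALSE, types = NULL, reason = "monomorphic")
}

#' Validate all sites of an allele-count table
#'
#' Applies [classifySite()] to every site, pooling counts over all
#' bulk-condition cells (or over the bulks of one `condition`), and returns
#' the passing sites with their counts collapsed onto the two retained
#' SNP-types per cell.  Reads of non-retained types (at most 10% of a
#' passing site by construction) are dropped.
#'
#' @param x an [AlleleCountTable-class].
#' @param cfg a [snpFilterConfig()].
#' @param condition pool only this condition's cells for typing; default
#'   pools everything.
#' @return list with `table` (an AlleleCountTable whose type dimension is
#'   `allele_a`/`allele_b`, the retained bases sitting in
#'   `mcols(siteRanges(.))`) and `summary` (named counts per decision,
#'   partitioning the input sites).
#' @export
filterSites <- function(x, cfg = snpFilterConfig(), condition = NULL) {
  if (length(x) == 0L) stop("empty allele-count table")
  pooled <- pooledCounts(x, condition = condition)
  reasons <- character(length(x))
  typeA <- typeB <- character(length(x))
  for (i in seq_len(length(x))) {
    dec <- classifySite(pooled[i, ], cfg)
    reasons[i] <- dec$reason
    if (dec$pass) {
      typeA[i] <- dec$types[1L]
      typeB[i] <- dec$types[2L]
    }
  }
  lev <- c("pass", "monomorphic", "too_many_types", "low_type_support",
           "low_combined_fraction")
  summary <- table(factor(reasons, levels = lev))
  keep <- which(reasons == "pass")
  gr <- siteRanges(x)[keep]
  mcols(gr)$allele_a <- typeA[keep]
  mcols(gr)$allele_b <- typeB[keep]
  bulks <- bulkNames(x); conds <- conditionNames(x); types <- typeNames(x)
  cnt <- array(0L, dim = c(length(keep), 2L, length(bulks), length(conds)),
               dimnames = list(NULL, c("allele_a", "allele_b"), bulks, conds))
  for (k in seq_along(keep)) {
    i <- keep[k]
    cnt[k, 1L, , ] <- x@counts[i, match(typeA[i], types), , ]
    cnt[k, 2L, , ] <- x@counts[i, match(typeB[i], types), , ]
  }
  tab <- AlleleCountTable(gr, cnt,
                          metadata = c(x@metadata,
                                       list(filter_summary = c(summary))))
  list(table = tab, summary = stats::setNames(as.integer(summary), lev))
}
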