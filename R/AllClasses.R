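#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom S4Vectors DataFrame metadata mcols mcols<- SimpleList
#' @importFrom GenomicRanges GRanges granges seqnames start end width
#' @importFrom IRanges IRanges subsetByOverlaps findOverlaps
NULL

## ---------------------------------------------------------------------------
## Central data containers
## ---------------------------------------------------------------------------

#' AlleleCountTable: per-site allele depths for a two-bulk design
#'
#' Holds read counts of the observed SNP-types (bases, or the two retained
#' alleles of a validated site) at a set of genomic positions, stratified by
#' bulk (e.g. tolerant/sensitive pool) and experimental condition
#' (e.g. normal/waterlogged).  Counts live in a 4-d integer array
#' `sites x types x bulks x conditions`; site coordinates are a
#' [GenomicRanges::GRanges] of width-1 positions (1-based).
#'
#' @slot rowRanges GRanges of SNP positions, one per site.  After site
#'   validation ([filterSites()]) the mcols carry `allele_a`/`allele_b`,
#'   the two retained SNP-types (descending pooled count).
#' @slot counts integer array with `dimnames` on the type, bulk and
#'   condition dimensions.
#' @slot metadata list of provenance (load summaries, filter summaries).
#' @export
setClass("AlleleCountTable",
  slots = c(rowRanges = "GRanges", counts = "array", metadata = "list"))

setValidity("AlleleCountTable", function(object) {
  cnt <- object@counts
  if (length(dim(cnt)) != 4L)
    return("'counts' must be a 4-d array (site x type x bulk x condition)")
  if (dim(cnt)[1L] != length(object@rowRanges))
    return("first dimension of 'counts' must match length(rowRanges)")
  dn <- dimnames(cnt)
  if (is.null(dn) || any(vapply(dn[2:4], is.null, logical(1))))
    return("type, bulk and condition dimensions must be named")
  if (anyNA(cnt) || any(cnt < 0))
    return("counts must be non-negative and non-missing")
  key <- paste0(as.character(seqnames(object@rowRanges)), ":",
                start(object@rowRanges))
  if (anyDuplicated(key))
    return("duplicated (chrom, pos) sites are not allowed")
  if (any(width(object@rowRanges) != 1L))
    return("sites must be width-1 positions")
  TRUE
})

#' ExpressionMatrix: gene-level read counts with lengths and library sizes
#'
#' A [SummarizedExperiment::SummarizedExperiment] with a single `counts`
#' assay, per-gene lengths in `rowData(x)$gene_length` (bp) and per-sample
#' library sizes in `colData(x)$library_size` (reads).
#'
#' @export
setClass("ExpressionMatrix", contains = "SummarizedExperiment")

setValidity("ExpressionMatrix", function(object) {
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    return("an ExpressionMatrix needs a 'counts' assay")
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (is.null(rd$gene_length))
    return("rowData must carry 'gene_length'")
  if (is.null(cd$library_size))
    return("colData must carry 'library_size'")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(cnt) || any(cnt < 0))
    return("counts must be non-negative")
  if (any(rd$gene_length <= 0))
    return("gene lengths must be positive")
  if (anyDuplicated(rownames(object)))
    return("duplicated gene ids")
  TRUE
})

#' DegTable: one differential-expression contrast
#'
#' A `DFrame` subclass, one row per tested gene, with pooled counts and
#' library sizes per side, mean RPKM per side, a fold change `>= 1` with its
#' direction (`"up"` means higher on side A), the digital-tag test p-value,
#' its BH-adjusted FDR, the significance call, and the fold-change magnitude
#' bin of significant genes.  Contrast labels and the [degConfig()] used sit
#' in `metadata()`.
#'
#' @export
setClass("DegTable", contains = "DFrame")

.DEG_COLUMNS <- c("gene_id", "count_a", "count_b", "lib_a", "lib_b",
                  "rpkm_a", "rpkm_b", "fold_change", "direction",
                  "pvalue", "fdr", "significant", "bin")

setValidity("DegTable", function(object) {
  if (!all(.DEG_COLUMNS %in% colnames(object)))
    return(paste("missing columns:",
                 paste(setdiff(.DEG_COLUMNS, colnames(object)), collapse = ", ")))
  if (any(object$fold_change < 1, na.rm = TRUE))
    return("fold_change must be >= 1 (direction is carried separately)")
  if (!all(object$direction %in% c("up", "down")))
    return("direction must be 'up' or 'down'")
  TRUE
})

#' PanelTruth: ground truth of a simulated two-bulk panel
#'
#' @slot sites GRanges of simulated SNPs with mcols `coupling` (probability
#'   that a line carries the causal-coupled allele given its causal-locus
#'   allele), `f_tolerant`/`f_sensitive` (true carrier fractions of the
#'   tolerant-coupled allele), `linked` (coupling at or above the configured
#'   cutoff), and `allele_a`/`allele_b` (the tolerant-coupled base and the
#'   alternative base).
#' @slot genoTolerant,genoSensitive logical line-by-SNP matrices: does the
#'   line carry the tolerant-coupled allele?
#' @slot causal GRanges of length 1, the causal locus.
#' @slot config the [simulationConfig()] that produced the panel.
#' @export
setClass("PanelTruth",
  slots = c(sites = "GRanges", genoTolerant = "matrix",
            genoSensitive = "matrix", causal = "GRanges",
            config = "ANY"))

setValidity("PanelTruth", function(object) {
  n <- length(object@sites)
  if (ncol(object@genoTolerant) != n || ncol(object@genoSensitive) != n)
    return("genotype matrices must have one column per SNP")
  need <- c("coupling", "f_tolerant", "f_sensitive", "linked",
            "allele_a", "allele_b")
  if (!all(need %in% colnames(mcols(object@sites))))
    return("truth mcols incomplete")
  fT <- mcols(object@sites)$f_tolerant
  mT <- nrow(object@genoTolerant)
  if (any(abs(fT * mT - round(fT * mT)) > 1e-8))
    return("f_tolerant must lie on the k/m lattice")
  TRUE
})

## ---------------------------------------------------------------------------
## Configuration objects
## ---------------------------------------------------------------------------

setClass("ReadQcConfig",
  representation(max_n_fraction = "numeric", low_quality_phred = "integer",
                 max_low_quality_fraction = "numeric"))

setClass("SnpFilterConfig",
  representation(min_type_reads = "integer", min_type_fraction = "numeric",
                 min_two_type_fraction = "numeric"))

setClass("LinkageModelConfig",
  representation(prior_linked = "numeric",
                 alpha_linked = "numeric", beta_linked = "numeric",
                 alpha_null = "numeric", beta_null = "numeric",
                 null_mode = "character",
                 call_threshold = "numeric",
                 em_enabled = "logical", em_tol = "numeric",
                 em_max_iter = "integer"))

setClass("DegConfig",
  representation(fold_change_threshold = "numeric", fdr_threshold = "numeric",
                 pseudocount_rpkm = "numeric", replicate_handling = "character"))

setClass("SimulationConfig",
  representation(n_tolerant_lines = "integer", n_sensitive_lines = "integer",
                 chromosomes = "numeric", n_snps = "integer",
                 causal_chrom = "character", causal_pos = "numeric",
                 ld_decay_length = "numeric", linked_coupling = "numeric",
                 mean_depth = "numeric", base_error = "numeric",
                 n_replicates = "integer", n_genes = "integer",
                 n_de_genes = "integer", de_log2fc = "numeric",
                 nb_dispersion = "numeric", library_size_mean = "numeric",
                 seed = "integer"))

setClass("PipelineConfig",
  representation(read_qc = "ReadQcConfig", snp_filter = "SnpFilterConfig",
                 linkage = "LinkageModelConfig", deg = "DegConfig",
                 simulation = "SimulationConfig", seed = "integer",
                 outdir = "character", log_level = "character"))

setValidity("ReadQcConfig", function(object) {
  if (object@max_n_fraction < 0 || object@max_n_fraction > 1 ||
      object@max_low_quality_fraction < 0 || object@max_low_quality_fraction > 1)
    return("fractions must be in [0, 1]")
  if (object@low_quality_phred < 0L) return("phred cutoff must be >= 0")
  TRUE
})

setValidity("SnpFilterConfig", function(object) {
  if (object@min_type_reads < 0L) return("min_type_reads must be >= 0")
  if (object@min_type_fraction < 0 || object@min_type_fraction > 1 ||
      object@min_two_type_fraction < 0 || object@min_two_type_fraction > 1)
    return("fractions must be in [0, 1]")
  if (2 * object@min_type_fraction > 1)
    return("two types cannot each require more than half the reads")
  TRUE
})

setValidity("LinkageModelConfig", function(object) {
  if (any(c(object@alpha_linked, object@beta_linked,
            object@alpha_null, object@beta_null) <= 0))
    return("pseudo-counts must be positive")
  if (object@prior_linked < 0 || object@prior_linked > 1)
    return("prior_linked must be in [0, 1]")
  if (object@call_threshold <= 0 || object@call_threshold >= 1)
    return("call_threshold must be in (0, 1)")
  if (!object@null_mode %in% c("shared", "half"))
    return("null_mode must be 'shared' or 'half'")
  TRUE
})

setValidity("DegConfig", function(object) {
  if (object@fold_change_threshold <= 1)
    return("fold_change_threshold must exceed 1")
  if (object@fdr_threshold <= 0 || object@fdr_threshold >= 1)
    return("fdr_threshold must be in (0, 1)")
  if (object@pseudocount_rpkm < 0) return("pseudocount must be >= 0")
  if (object@replicate_handling != "pool_sum")
    return("only replicate_handling = 'pool_sum' is supported")
  TRUE
})

setValidity("SimulationConfig", function(object) {
  if (object@n_tolerant_lines < 1L || object@n_sensitive_lines < 1L)
    return("each bulk needs at least one line")
  if (is.null(names(object@chromosomes)) || any(object@chromosomes <= 0))
    return("chromosomes must be a named vector of positive lengths")
  if (!object@causal_chrom %in% names(object@chromosomes))
    return("causal locus must lie on a listed chromosome")
  if (object@causal_pos < 1 ||
      object@causal_pos > object@chromosomes[[object@causal_chrom]])
    return("causal position outside its chromosome")
  if (object@ld_decay_length <= 0) return("ld_decay_length must be positive")
  if (object@base_error < 0 || object@base_error >= 0.5)
    return("base_error must be in [0, 0.5)")
  if (object@mean_depth < 0) return("mean_depth must be >= 0")
  if (object@n_de_genes > object@n_genes)
    return("cannot plant more DE genes than genes")
  TRUE
})
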