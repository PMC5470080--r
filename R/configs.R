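## Constructor functions for the configuration objects.  Defaults are the
## thresholds the analysis is defined with: read QC at 5% N / Q10 / 20%,
## site validation at 3 reads / 20% / 90%, linkage calls at posterior > 0.9,
## DEGs at > 2-fold and FDR <= 0.001.

#' Read-QC thresholds
#'
#' A read is discarded when its fraction of N bases exceeds
#' `max_n_fraction`, or when the fraction of bases at or below
#' `low_quality_phred` exceeds `max_low_quality_fraction`.
#'
#' @param max_n_fraction maximum tolerated fraction of unknown (N) bases.
#' @param low_quality_phred phred score at or below which a base counts as
#'   low quality.
#' @param max_low_quality_fraction maximum tolerated fraction of low-quality
#'   bases.
#' @return a `ReadQcConfig` object for [filterFastq()].
#' @export
readQcConfig <- function(max_n_fraction = 0.05, low_quality_phred = 10L,
                         max_low_quality_fraction = 0.20) {
  new("ReadQcConfig", max_n_fraction = max_n_fraction,
      low_quality_phred = as.integer(low_quality_phred),
      max_low_quality_fraction = max_low_quality_fraction)
}

#' SNP-site validation thresholds
#'
#' A base qualifies as a SNP-type when it has at least `min_type_reads`
#' pooled reads and at least `min_type_fraction` of the pooled site total; a
#' site is valid when exactly two bases qualify and together they hold at
#' least `min_two_type_fraction` of the total.
#'
#' @param min_type_reads minimum reads per qualifying SNP-type.
#' @param min_type_fraction minimum fraction of the site total per type.
#' @param min_two_type_fraction minimum combined fraction of the two types.
#' @return a `SnpFilterConfig` for [classifySite()] / [filterSites()].
#' @export
snpFilterConfig <- function(min_type_reads = 3L, min_type_fraction = 0.20,
                            min_two_type_fraction = 0.90) {
  new("SnpFilterConfig", min_type_reads = as.integer(min_type_reads),
      min_type_fraction = min_type_fraction,
      min_two_type_fraction = min_two_type_fraction)
}

#' Linkage-probability model settings
#'
#' Settings of the two-hypothesis beta-binomial model behind
#' [linkagePosterior()]: under linkage each bulk has its own allele
#' frequency with a Beta(`alpha_linked`, `beta_linked`) prior; under the
#' null both bulks share one frequency with a Beta(`alpha_null`,
#' `beta_null`) prior (`null_mode = "shared"`), or the frequency is pinned
#' at 1/2 (`null_mode = "half"`).  `prior_linked` is the prior probability
#' that a site is linked; with `em_enabled` it is replaced by the
#' empirical-Bayes estimate from [estimatePrior()].
#'
#' @param prior_linked prior probability of linkage; small, because a single
#'   causal region is expected in a genome-wide scan.
#' @param alpha_linked,beta_linked Beta pseudo-counts under linkage.
#' @param alpha_null,beta_null Beta pseudo-counts under the null.
#' @param null_mode `"shared"` (one free shared frequency) or `"half"`
#'   (fixed at 0.5).
#' @param call_threshold posterior above which a SNP is called
#'   high-probability (strict inequality).
#' @param em_enabled estimate `prior_linked` by EM across all sites.
#' @param em_tol,em_max_iter EM stopping rules.
#' @return a `LinkageModelConfig`.
#' @export
linkageModelConfig <- function(prior_linked = 0.05,
                               alpha_linked = 1, beta_linked = 1,
                               alpha_null = 1, beta_null = 1,
                               null_mode = c("shared", "half"),
                               call_threshold = 0.9,
                               em_enabled = FALSE, em_tol = 1e-6,
                               em_max_iter = 100L) {
  new("LinkageModelConfig", prior_linked = prior_linked,
      alpha_linked = alpha_linked, beta_linked = beta_linked,
      alpha_null = alpha_null, beta_null = beta_null,
      null_mode = match.arg(null_mode), call_threshold = call_threshold,
      em_enabled = em_enabled, em_tol = em_tol,
      em_max_iter = as.integer(em_max_iter))
}

#' Differential-expression calling settings
#'
#' @param fold_change_threshold a gene is significant only when its RPKM
#'   fold change strictly exceeds this (default: two-fold).
#' @param fdr_threshold BH-adjusted significance gate.
#' @param pseudocount_rpkm added to both sides of the RPKM ratio so genes
#'   silent on one side still yield a finite (possibly very large) fold
#'   change.
#' @param replicate_handling only `"pool_sum"`: replicate counts are summed
#'   into one library per side before the digital-tag test.
#' @return a `DegConfig` for [callDegs()].
#' @export
degConfig <- function(fold_change_threshold = 2, fdr_threshold = 0.001,
                      pseudocount_rpkm = 0.01,
                      replicate_handling = "pool_sum") {
  new("DegConfig", fold_change_threshold = fold_change_threshold,
      fdr_threshold = fdr_threshold, pseudocount_rpkm = pseudocount_rpkm,
      replicate_handling = replicate_handling)
}

#' Synthetic two-bulk study configuration
#'
#' Defaults mirror the study design the package targets: a tolerant bulk
#' pooled from 8 inbred lines against a sensitive bulk of 10, two
#' conditions with three biological replicates of pooled-RNA expression, a
#' single causal locus whose allele coupling decays exponentially with
#' distance, and Poisson sequencing depth with a small per-read base-error
#' rate.
#'
#' @param n_tolerant_lines,n_sensitive_lines inbred lines per bulk.
#' @param chromosomes named vector of chromosome lengths in bp.
#' @param n_snps number of simulated SNPs (the causal site is always
#'   included as one of them).
#' @param causal_chrom,causal_pos causal locus coordinates.
#' @param ld_decay_length bp scale of the exponential allele-coupling decay
#'   `c(d) = 0.5 + 0.5 exp(-d / ld_decay_length)`.
#' @param linked_coupling coupling at or above which a SNP is flagged as
#'   truly linked in the ground truth.
#' @param mean_depth expected reads per site per bulk-condition cell.
#' @param base_error per-read miscall probability.
#' @param n_replicates biological replicates per bulk-condition cell.
#' @param n_genes,n_de_genes genes simulated / genes with a planted
#'   bulk-divergent expression effect.
#' @param de_log2fc magnitude of the planted log2 fold change (sign drawn
#'   per gene).
#' @param nb_dispersion negative-binomial dispersion of replicate counts.
#'   Small by default: replicates are re-sequenced pools of the same 8-10
#'   inbred lines, so line-to-line biological variance is largely averaged
#'   out.
#' @param library_size_mean expected reads per replicate library.
#' @param seed integer seed; `NA` leaves the ambient RNG state untouched.
#' @return a `SimulationConfig`.
#' @export
simulationConfig <- function(n_tolerant_lines = 8L, n_sensitive_lines = 10L,
                             chromosomes = c(chr1 = 3e7, chr2 = 3e7,
                                             chr3 = 3e7, chr4 = 3e7,
                                             chr5 = 3e7),
                             n_snps = 2000L,
                             causal_chrom = "chr1", causal_pos = 1.5e7,
                             ld_decay_length = 1e7, linked_coupling = 0.95,
                             mean_depth = 50, base_error = 0.01,
                             n_replicates = 3L,
                             n_genes = 2000L, n_de_genes = 100L,
                             de_log2fc = 3, nb_dispersion = 0.01,
                             library_size_mean = 2e6,
                             seed = NA_integer_) {
  new("SimulationConfig",
      n_tolerant_lines = as.integer(n_tolerant_lines),
      n_sensitive_lines = as.integer(n_sensitive_lines),
      chromosomes = chromosomes, n_snps = as.integer(n_snps),
      causal_chrom = causal_chrom, causal_pos = causal_pos,
      ld_decay_length = ld_decay_length, linked_coupling = linked_coupling,
      mean_depth = mean_depth, base_error = base_error,
      n_replicates = as.integer(n_replicates),
      n_genes = as.integer(n_genes), n_de_genes = as.integer(n_de_genes),
      de_log2fc = de_log2fc, nb_dispersion = nb_dispersion,
      library_size_mean = library_size_mean, seed = as.integer(seed))
}

#' Whole-pipeline configuration
#'
#' Bundles the per-stage configurations, a global seed and an output
#' directory for [runPipeline()].
#'
#' @param read_qc,snp_filter,linkage,deg,simulation stage configurations;
#'   defaults are the package defaults.
#' @param seed global integer seed; it overrides `simulation@seed`.
#' @param outdir directory for stage outputs and the run manifest.
#' @param log_level `"info"` or `"quiet"`.
#' @return a `PipelineConfig`.
#' @export
pipelineConfig <- function(read_qc = readQcConfig(),
                           snp_filter = snpFilterConfig(),
                           linkage = linkageModelConfig(),
                           deg = degConfig(),
                           simulation = simulationConfig(),
                           seed = 1L, outdir = tempfile("bsrseq_run_"),
                           log_level = c("info", "quiet")) {
  new("PipelineConfig", read_qc = read_qc, snp_filter = snp_filter,
      linkage = linkage, deg = deg, simulation = simulation,
      seed = as.integer(seed), outdir = outdir,
      log_level = match.arg(log_level))
}
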