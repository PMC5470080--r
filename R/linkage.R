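## Bayesian linkage probability for bulked segregant designs.
##
## At a validated biallelic site with per-bulk counts (a_T, b_T) and
## (a_S, b_S) of the two retained alleles, two hypotheses are compared:
##
##   H1 (linked):   each bulk has its own allele frequency p_T, p_S with
##                  independent Beta(alpha_linked, beta_linked) priors, so
##                  L1 = m(a_T, b_T) * m(a_S, b_S);
##   H0 (unlinked): both bulks share one frequency with a
##                  Beta(alpha_null, beta_null) prior, so
##                  L0 = m(a_T + a_S, b_T + b_S)  (null_mode "shared"),
##                  or the frequency is pinned at 1/2 (null_mode "half").
##
## m(a, b) is the beta-binomial marginal with the binomial coefficient
## omitted: it is identical between hypotheses and cancels in the Bayes
## factor.  The posterior is pi * L1 / (pi * L1 + (1 - pi) * L0), computed
## in log space.  The shared-frequency null is the default because bulks
## of unrelated inbreds need not sit at frequency 1/2 at unlinked sites.

#' Log marginal likelihood of a beta-binomial count pair
#'
#' Returns `log[B(a + alpha, b + beta) / B(alpha, beta)]`, the marginal
#' probability of observing `a` reads of one allele and `b` of the other
#' with the frequency integrated out against a Beta(alpha, beta) prior
#' (binomial coefficient omitted; it cancels between hypotheses).
#' Vectorised over `a` and `b`.
#'
#' @param a,b non-negative allele read counts.
#' @param alpha,beta positive Beta pseudo-counts.
#' @return log marginal likelihood(s).
#' @export
logMarginalBetaBinomial <- function(a, b, alpha = 1, beta = 1) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("pseudo-counts must be positive")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  lbeta(a + alpha, b + beta) - lbeta(alpha, beta)
}

#' Posterior linkage probability from two-bulk allele counts
#'
#' @param a_t,b_t reads of allele one / allele two in the first (tolerant)
#'   bulk; vectorised over sites.
#' @param a_s,b_s same for the second (sensitive) bulk.
#' @param cfg a [linkageModelConfig()].
#' @param prior optional prior probability of linkage overriding
#'   `cfg@prior_linked` (used after EM estimation).
#' @return data.frame with `log_bf` (log Bayes factor `log(L1/L0)`) and
#'   `posterior`.
#' @export
linkagePosterior <- function(a_t, b_t, a_s, b_s, cfg = linkageModelConfig(),
                             prior = NULL) {
  if (any(a_t + b_t + a_s + b_s == 0))
    stop("undefined result: site with zero reads in both bulks")
  logBF <- linkageLogBF(a_t, b_t, a_s, b_s, cfg)
  pi <- if (is.null(prior)) cfg@prior_linked else prior
  data.frame(log_bf = logBF, posterior = .posteriorFromLogBF(logBF, pi))
}

## log Bayes factor only (shared by the posterior and the EM prior fit)
linkageLogBF <- function(a_t, b_t, a_s, b_s, cfg) {
  logL1 <- logMarginalBetaBinomial(a_t, b_t, cfg@alpha_linked, cfg@beta_linked) +
    logMarginalBetaBinomial(a_s, b_s, cfg@alpha_linked, cfg@beta_linked)
  logL0 <- switch(cfg@null_mode,
    shared = logMarginalBetaBinomial(a_t + a_s, b_t + b_s,
                                     cfg@alpha_null, cfg@beta_null),
    half = (a_t + b_t + a_s + b_s) * log(0.5))
  logL1 - logL0
}

.posteriorFromLogBF <- function(logBF, pi) {
  if (pi <= 0) return(rep(0, length(logBF)))
  if (pi >= 1) return(rep(1, length(logBF)))
  stats::plogis(stats::qlogis(pi) + logBF)
}

#' Empirical-Bayes estimate of the linked-site prior
#'
#' Fits the mixture weight pi of the two-component (linked/unlinked)
#' marginal across sites by EM: the E-step computes each site's posterior
#' at the current pi, the M-step replaces pi by their mean.  The mixture
#' log-likelihood is non-decreasing across iterations (standard EM
#' guarantee, also returned for inspection).
#'
#' @param log_bf per-site log Bayes factors (from [linkagePosterior()] or
#'   [scanLinkage()]); at least 10 sites.
#' @param cfg a [linkageModelConfig()]; `prior_linked` initialises pi.
#' @return list with `pi` (clamped to `[1e-6, 0.5]`), `iterations`,
#'   `converged` and `log_lik` (trajectory, one value per iteration).
#' @export
estimatePrior <- function(log_bf, cfg = linkageModelConfig()) {
  if (length(log_bf) < 10L)
    stop("too few sites to estimate a prior; use a fixed prior_linked")
  pi <- min(max(cfg@prior_linked, 1e-6), 0.5)
  ll <- numeric(0)
  converged <- FALSE
  iter <- 0L
  mixLogLik <- function(p) {
    a <- log(p) + log_bf          # linked component (relative to L0)
    b <- rep(log1p(-p), length(log_bf))
    m <- pmax(a, b)
    sum(m + log(exp(a - m) + exp(b - m)))
  }
  for (iter in seq_len(cfg@em_max_iter)) {
    post <- .posteriorFromLogBF(log_bf, pi)
    piNew <- mean(post)
    ll <- c(ll, mixLogLik(pi))
    if (abs(piNew - pi) < cfg@em_tol) {
      pi <- piNew
      converged <- TRUE
      break
    }
    pi <- piNew
  }
  list(pi = min(max(pi, 1e-6), 0.5), iterations = iter,
       converged = converged, log_lik = ll)
}

#' Score every site of a filtered allele-count table for one condition
#'
#' Extracts the two retained-allele counts of each bulk under `condition`,
#' computes the log Bayes factor and posterior for every site and
#' optionally replaces the prior with its EM estimate.
#'
#' @param x a filtered [AlleleCountTable-class] (type dimension
#'   `allele_a`/`allele_b`, exactly two bulks).
#' @param condition condition name to score.
#' @param cfg a [linkageModelConfig()].
#' @return GRanges, one range per scored site, with mcols `allele_a`,
#'   `allele_b`, the four counts, `log_bf`, `posterior` and `high_prob`
#'   (`posterior > cfg@call_threshold`, strict).  Sites with zero reads in
#'   both bulks under this condition are dropped with a warning.  The
#'   prior actually used (and the EM fit, if any) sits in `metadata()`.
#' @export
scanLinkage <- function(x, condition, cfg = linkageModelConfig()) {
  if (!identical(typeNames(x), c("allele_a", "allele_b")))
    stop("scanLinkage needs a filtered table (run filterSites first)")
  bulks <- bulkNames(x)
  if (length(bulks) != 2L) stop("exactly two bulks are required")
  if (!condition %in% conditionNames(x))
    stop("unknown condition: ", condition)
  ci <- match(condition, conditionNames(x))
  a_t <- x@counts[, 1L, 1L, ci]
  b_t <- x@counts[, 2L, 1L, ci]
  a_s <- x@counts[, 1L, 2L, ci]
  b_s <- x@counts[, 2L, 2L, ci]
  ok <- (a_t + b_t + a_s + b_s) > 0
  if (!all(ok)) {
    warning(sum(!ok), " sites with no reads under condition '", condition,
            "' dropped")
  }
  gr <- siteRanges(x)[ok]
  logBF <- linkageLogBF(a_t[ok], b_t[ok], a_s[ok], b_s[ok], cfg)
  pi <- cfg@prior_linked
  emFit <- NULL
  if (cfg@em_enabled) {
    emFit <- estimatePrior(logBF, cfg)
    pi <- emFit$pi
  }
  post <- .posteriorFromLogBF(logBF, pi)
  mcols(gr) <- DataFrame(allele_a = mcols(siteRanges(x))$allele_a[ok],
                         allele_b = mcols(siteRanges(x))$allele_b[ok],
                         count_a_t = a_t[ok], count_b_t = b_t[ok],
                         count_a_s = a_s[ok], count_b_s = b_s[ok],
                         log_bf = logBF, posterior = post,
                         high_prob = post > cfg@call_threshold)
  metadata(gr) <- list(condition = condition, prior = pi, em = emFit,
                       bulks = bulks, threshold = cfg@call_threshold)
  gr
}

#' Call high-probability SNPs
#'
#' Strict threshold, matching the ">0.9" call rule: a SNP is called when
#' its posterior strictly exceeds `threshold`.  Output is sorted by
#' (chromosome, position), chromosome names lexicographically.
#'
#' @param results GRanges from [scanLinkage()].
#' @param threshold posterior cut, default 0.9.
#' @return the called subset, sorted.
#' @export
callHighProbability <- function(results, threshold = 0.9) {
  called <- results[results$posterior > threshold]
  called[order(as.character(seqnames(called)), start(called))]
}

#' Intersect two conditions' high-probability SNP sets
#'
#' SNPs are keyed by (chromosome, position, unordered retained-type pair);
#' a SNP overlaps when the same site with the same two alleles is called
#' under both conditions.
#'
#' @param set_a,set_b called GRanges (from [callHighProbability()]) for the
#'   two conditions.
#' @return list with `overlap` (GRanges keyed like `set_a`, carrying both
#'   conditions' posteriors as `posterior_a`/`posterior_b`), `n_only_a`,
#'   `n_only_b`.
#' @export
intersectHighProbability <- function(set_a, set_b) {
  key <- function(g) {
    pair <- ifelse(g$allele_a < g$allele_b,
                   paste0(g$allele_a, g$allele_b),
                   paste0(g$allele_b, g$allele_a))
    paste0(as.character(seqnames(g)), ":", start(g), ":", pair)
  }
  ka <- key(set_a); kb <- key(set_b)
  shared <- intersect(ka, kb)
  ia <- match(shared, ka); ib <- match(shared, kb)
  overlap <- set_a[ia]
  mcols(overlap)$posterior_a <- set_a$posterior[ia]
  mcols(overlap)$posterior_b <- set_b$posterior[ib]
  overlap <- overlap[order(as.character(seqnames(overlap)), start(overlap))]
  list(overlap = overlap,
       n_only_a = length(set_a) - length(shared),
       n_only_b = length(set_b) - length(shared))
}

#' Assign SNPs to the gene models containing them
#'
#' A SNP is assigned to every gene whose 1-based inclusive span contains
#' its position; strand is ignored.  SNPs inside no gene are labelled
#' `"intergenic"`.
#'
#' @param snps GRanges of SNPs.
#' @param genes GRanges of gene models with `gene_id` (from
#'   [readGeneModels()]).
#' @return list with `snps` (input plus a `gene_ids` mcol,
#'   comma-collapsed, `"intergenic"` when unassigned), `gene_counts`
#'   (data.frame `gene_id`, `n_snps` for genes holding at least one SNP)
#'   and `histogram` (how many genes carry 1, 2, 3, ... SNPs).
#' @export
assignSnpsToGenes <- function(snps, genes) {
  hits <- findOverlaps(snps, genes, ignore.strand = TRUE)
  ids <- rep("intergenic", length(snps))
  if (length(hits)) {
    byQ <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                 S4Vectors::queryHits(hits))
    ids[as.integer(names(byQ))] <-
      vapply(byQ, function(g) paste(sort(g), collapse = ","), character(1))
  }
  out <- snps
  mcols(out)$gene_ids <- ids
  perGene <- table(genes$gene_id[S4Vectors::subjectHits(hits)])
  geneCounts <- data.frame(gene_id = names(perGene),
                           n_snps = as.integer(perGene),
                           stringsAsFactors = FALSE)
  geneCounts <- geneCounts[order(-geneCounts$n_snps, geneCounts$gene_id), ,
                           drop = FALSE]
  rownames(geneCounts) <- NULL
  histogram <- table(factor(geneCounts$n_snps))
  list(snps = out, gene_counts = geneCounts, histogram = histogram)
}

#' Per-chromosome counts of a SNP set
#'
#' @param snps GRanges.
#' @param chromosomes chromosome names to report; defaults to the
#'   seqlevels of `snps`.  Chromosomes without calls are reported as 0.
#' @return named integer vector; its sum equals `length(snps)` when
#'   `chromosomes` covers all seqlevels.
#' @export
summarizeByChromosome <- function(snps, chromosomes = NULL) {
  if (is.null(chromosomes))
    chromosomes <- GenomeInfoDb::seqlevels(snps)
  tab <- table(factor(as.character(seqnames(snps)), levels = chromosomes))
  stats::setNames(as.integer(tab), chromosomes)
}
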