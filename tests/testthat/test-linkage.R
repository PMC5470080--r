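## Beta-binomial linkage model, checked against the quadrature oracles in
## helper-oracles.R (independent of the log-gamma implementation path).

test_that("beta-binomial marginal matches closed forms and quadrature", {
  expect_equal(logMarginalBetaBinomial(0, 0, 1, 1), 0)
  expect_equal(logMarginalBetaBinomial(1, 0, 1, 1), log(1 / 2))
  expect_equal(logMarginalBetaBinomial(5, 2, 1, 1), log(quadMarginal(5, 2)),
               tolerance = 1e-10)
  set.seed(4)
  for (i in 1:20) {
    ab <- sample(0:40, 2)
    hp <- runif(2, 0.2, 4)
    got <- logMarginalBetaBinomial(ab[1], ab[2], hp[1], hp[2])
    ## quadrature against the full beta-binomial integrand
    ref <- stats::integrate(function(p)
      p^(ab[1]) * (1 - p)^(ab[2]) * stats::dbeta(p, hp[1], hp[2]),
      0, 1, rel.tol = 1e-13, abs.tol = 0)$value
    expect_equal(got, log(ref), tolerance = 1e-9)
  }
  expect_error(logMarginalBetaBinomial(1, 1, 0, 1), "positive")
})

test_that("fully divergent and balanced count patterns behave as derived", {
  ## (30,0,0,30): L1 = (1/31)^2, L0 = B(31,31) -> posterior > 0.99
  r <- linkagePosterior(30, 0, 0, 30)
  expect_equal(r$log_bf, log((1 / 31)^2) - lbeta(31, 31), tolerance = 1e-12)
  expect_gt(r$posterior, 0.99)
  expect_equal(r$posterior, quadPosterior(30, 0, 0, 30), tolerance = 1e-10)
  ## (5,5,5,5): BF = B(6,6)^2 / B(11,11) < 1, posterior < pi for any pi
  r2 <- linkagePosterior(5, 5, 5, 5)
  expect_equal(r2$log_bf, 2 * lbeta(6, 6) - lbeta(11, 11), tolerance = 1e-12)
  expect_lt(r2$log_bf, 0)
  for (pi in c(0.01, 0.3, 0.8, 0.99)) {
    expect_lt(linkagePosterior(5, 5, 5, 5,
                               linkageModelConfig(prior_linked = pi))$posterior,
              pi)
  }
})

test_that("prior degeneracy pins the posterior at 0 or 1", {
  cfg0 <- linkageModelConfig(prior_linked = 0)
  cfg1 <- linkageModelConfig(prior_linked = 1)
  expect_equal(linkagePosterior(30, 0, 0, 30, cfg0)$posterior, 0)
  expect_equal(linkagePosterior(5, 5, 5, 5, cfg1)$posterior, 1)
})

test_that("posterior agrees with quadrature on random bounded counts", {
  set.seed(12)
  for (i in 1:80) {
    nT <- sample(0:50, 1); nS <- sample(0:50, 1)
    if (nT + nS == 0) next
    aT <- sample(0:nT, 1); aS <- sample(0:nS, 1)
    got <- linkagePosterior(aT, nT - aT, aS, nS - aS)$posterior
    expect_equal(got, quadPosterior(aT, nT - aT, aS, nS - aS),
                 tolerance = 1e-8)
  }
})

test_that("type-swap and bulk-swap leave BF and posterior unchanged", {
  set.seed(13)
  for (i in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x) == 0) next
    r <- linkagePosterior(x[1], x[2], x[3], x[4])
    swapTypes <- linkagePosterior(x[2], x[1], x[4], x[3])
    swapBulks <- linkagePosterior(x[3], x[4], x[1], x[2])
    expect_equal(r$log_bf, swapTypes$log_bf, tolerance = 1e-12)
    expect_equal(r$log_bf, swapBulks$log_bf, tolerance = 1e-12)
    expect_equal(r$posterior, swapTypes$posterior, tolerance = 1e-12)
  }
})

test_that("Bayes factor grows with bulk divergence at fixed depth", {
  for (n in c(10L, 30L, 50L)) {
    ks <- seq(ceiling(n / 2), n)
    bf <- vapply(ks, function(k)
      linkagePosterior(k, n - k, n - k, k)$log_bf, numeric(1))
    expect_true(all(diff(bf) >= -1e-12))
  }
})

test_that("a site with no reads in either bulk is an error", {
  expect_error(linkagePosterior(0, 0, 0, 0), "zero reads")
})

test_that("the half null mode scores pooled counts against p = 1/2", {
  cfg <- linkageModelConfig(null_mode = "half")
  r <- linkagePosterior(8, 2, 3, 7, cfg)
  expectL0 <- 20 * log(0.5)
  expectL1 <- logMarginalBetaBinomial(8, 2) + logMarginalBetaBinomial(3, 7)
  expect_equal(r$log_bf, expectL1 - expectL0, tolerance = 1e-12)
})

test_that("high-probability calling is strict and sorted", {
  scan <- makeScan(c("chr2", "chr1", "chr1"), c(50L, 900L, 100L),
                   posterior = c(0.91, 0.90, 0.89))
  called <- callHighProbability(scan, 0.9)
  expect_equal(length(called), 1L)
  expect_equal(called$posterior, 0.91)
  expect_equal(length(callHighProbability(scan[integer(0)], 0.9)), 0L)
  all3 <- callHighProbability(scan, 0)
  expect_equal(length(all3), 3L)
  expect_equal(as.character(seqnames(all3)), c("chr1", "chr1", "chr2"))
  expect_equal(start(all3), c(100L, 900L, 50L))
})

test_that("cross-condition intersection is an exact keyed overlap", {
  a <- makeScan("chr1", c(10L, 20L, 30L), c(0.95, 0.96, 0.97))
  b <- makeScan("chr1", c(20L, 30L, 40L), c(0.93, 0.99, 0.91))
  ov <- intersectHighProbability(a, b)
  expect_equal(start(ov$overlap), c(20L, 30L))
  expect_equal(ov$n_only_a, 1L)
  expect_equal(ov$n_only_b, 1L)
  expect_equal(ov$overlap$posterior_b, c(0.93, 0.99))
  ## disjoint
  d <- intersectHighProbability(makeScan("chr1", 1L, 0.95),
                                makeScan("chr2", 1L, 0.95))
  expect_equal(length(d$overlap), 0L)
  ## subset
  s <- intersectHighProbability(a[1:2], a)
  expect_equal(length(s$overlap), 2L)
  ## same position, different retained pair -> no overlap
  m <- intersectHighProbability(makeScan("chr1", 10L, 0.95, "A", "G"),
                                makeScan("chr1", 10L, 0.95, "A", "T"))
  expect_equal(length(m$overlap), 0L)
  ## pair order within a site is ignored
  o <- intersectHighProbability(makeScan("chr1", 10L, 0.95, "A", "G"),
                                makeScan("chr1", 10L, 0.95, "G", "A"))
  expect_equal(length(o$overlap), 1L)
})

test_that("SNP-to-gene assignment is inclusive and handles overlaps", {
  genes <- makeGenes(c("g1", "g2"), "chr1", c(1000L, 1800L),
                     c(2000L, 2500L), strand = c("+", "-"))
  snps <- makeScan("chr1", c(1500L, 2000L, 3000L), c(0.95, 0.96, 0.97))
  res <- assignSnpsToGenes(snps, genes)
  expect_equal(res$snps$gene_ids, c("g1", "g1,g2", "intergenic"))
  expect_equal(res$gene_counts$n_snps[res$gene_counts$gene_id == "g1"], 2L)
  expect_equal(res$gene_counts$n_snps[res$gene_counts$gene_id == "g2"], 1L)
  expect_equal(as.integer(res$histogram[c("1", "2")]), c(1L, 1L))
})

test_that("per-chromosome counts conserve the set and report zeros", {
  snps <- makeScan(c("chr1", "chr1", "chr1", "chr2"),
                   c(1L, 2L, 3L, 4L), rep(0.95, 4))
  out <- summarizeByChromosome(snps, chromosomes = c("chr1", "chr2", "chr3"))
  expect_equal(out, c(chr1 = 3L, chr2 = 1L, chr3 = 0L))
  expect_equal(sum(out), length(snps))
  empty <- summarizeByChromosome(snps[integer(0)],
                                 chromosomes = c("chr1", "chr2"))
  expect_equal(sum(empty), 0L)
})

test_that("true linkage replicates across conditions; noise does not", {
  cfg <- simulationConfig(n_snps = 800L, seed = 55L)
  truth <- simulatePanel(cfg)
  act <- combineAlleleCounts(
    simulateAlleleCounts(truth, cfg, "normal", seed = 56L),
    simulateAlleleCounts(truth, cfg, "waterlogged", seed = 57L))
  filt <- filterSites(act)
  calls <- lapply(c("normal", "waterlogged"), function(cc)
    callHighProbability(scanLinkage(filt$table, cc)))
  ov <- intersectHighProbability(calls[[1]], calls[[2]])
  key <- function(g) paste0(as.character(seqnames(g)), ":", start(g))
  ## every SNP called under both conditions is in the intersection
  both <- intersect(key(calls[[1]]), key(calls[[2]]))
  expect_setequal(both, key(ov$overlap))
  ## intersection's off-chromosome fraction <= each single condition's
  offFrac <- function(g) {
    m <- match(key(g), key(truthSites(truth)))
    mean(as.character(seqnames(truthSites(truth)))[m] != "chr1")
  }
  expect_lte(offFrac(ov$overlap), offFrac(calls[[1]]))
  expect_lte(offFrac(ov$overlap), offFrac(calls[[2]]))
})
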