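## Digital expression: RPKM arithmetic, the two-library tag test against
## the log-gamma summation oracle and Monte Carlo, BH against the naive
## step-up reference (helper-oracles.R), and the planted-truth DEG calls.

test_that("RPKM follows its defining formula and scaling law", {
  em <- ExpressionMatrix(matrix(c(1000L, 0L), ncol = 1,
                               dimnames = list(c("g1", "g2"), "s1")),
                         geneLength = c(2000, 500), librarySize = 1e7)
  r <- computeRpkm(em)
  expect_equal(r["g1", "s1"], 50)
  expect_equal(r["g2", "s1"], 0)
  em2 <- ExpressionMatrix(matrix(c(1000L, 0L), ncol = 1,
                                dimnames = list(c("g1", "g2"), "s1")),
                          geneLength = c(2000, 500), librarySize = 2e7)
  expect_equal(computeRpkm(em2)["g1", "s1"], 25)
  emBad <- ExpressionMatrix(matrix(1L, dimnames = list("g1", "s1")),
                            geneLength = 100, librarySize = 0)
  expect_error(computeRpkm(emBad), "library sizes")
})

test_that("tag-test closed forms, normalisation and symmetry hold", {
  ## equal libraries, no tags on either side: p(0|0) = 1/2, p capped at 1
  expect_equal(oraclePredictive(0, 0, 1e6, 1e6), 0.5)
  expect_equal(acTest(0, 0, 1e6, 1e6), 1)
  ## p(0 | 1) = 1/4 with equal libraries
  expect_equal(oraclePredictive(0, 1, 1e6, 1e6), 0.25)
  ## predictive normalises to 1 (truncated at negligible tail mass)
  for (x in c(0, 3, 20, 100)) {
    for (r in c(0.5, 1, 2)) {
      s <- oracleLowerTail(3000, x, 1e6, r * 1e6)
      expect_lt(abs(s - 1), 1e-10)
    }
  }
  ## implementation tail equals the summation oracle
  for (x in c(0, 2, 20, 57)) {
    for (y in c(0, 1, 5, 40)) {
      expect_equal(stats::pnbinom(y, size = x + 1, prob = 0.4),
                   oracleLowerTail(y, x, 1e6, 1.5e6), tolerance = 1e-12)
    }
  }
  ## exact symmetry in (x, N1) <-> (y, N2)
  set.seed(41)
  for (i in 1:50) {
    x <- sample(0:100, 1); y <- sample(0:100, 1)
    n1 <- runif(1, 1e5, 1e7); n2 <- runif(1, 1e5, 1e7)
    expect_equal(acTest(x, y, n1, n2), acTest(y, x, n2, n1),
                 tolerance = 1e-6)
  }
})

test_that("tag-test p-value matches a large Monte-Carlo draw", {
  set.seed(42)
  x <- 20; y <- 2
  draws <- stats::rnbinom(1e6, size = x + 1, prob = 0.5)
  fHat <- mean(draws <= y)
  pHat <- min(1, 2 * min(fHat, 1 - fHat))
  se <- 2 * sqrt(fHat * (1 - fHat) / 1e6)
  expect_lt(abs(acTest(x, y, 1e6, 1e6) - pHat), 3 * se)
})

test_that("BH adjustment matches a naive quadratic step-up reference", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(rep(0.2, 7)), rep(0.2, 7))
  set.seed(43)
  for (i in 1:30) {
    p <- round(runif(sample(1:12, 1)), 3)
    expect_equal(bhAdjust(p), naiveBH(p), tolerance = 1e-12)
  }
  ## permutation stability
  p <- runif(9)
  perm <- sample(9)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical pooled counts under equal libraries are never called", {
  cnt <- matrix(rep(c(50L, 3L, 0L), 4), nrow = 3,
                dimnames = list(c("g1", "g2", "g0"),
                                c("a1", "a2", "b1", "b2")))
  em <- ExpressionMatrix(cnt, geneLength = c(1000, 1000, 1000),
                         librarySize = rep(1e6, 4))
  deg <- callDegs(em, c("a1", "a2"), c("b1", "b2"))
  ## the zero-on-both-sides gene is excluded from testing
  expect_equal(nrow(deg), 2L)
  expect_false("g0" %in% deg$gene_id)
  expect_equal(metadata(deg)$n_excluded_zero, 1L)
  expect_true(all(!deg$significant))
  expect_true(all(deg$pvalue > 0.5))
  expect_true(all(deg$fold_change == 1))
})

test_that("group-definition errors are caught", {
  cnt <- matrix(1L, 2, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  em <- ExpressionMatrix(cnt, geneLength = c(100, 100))
  expect_error(callDegs(em, character(0), "s2"), "empty")
  expect_error(callDegs(em, "s1", "s1"), "disjoint")
  expect_error(callDegs(em, "s1", "sX"), "unknown")
})

test_that("planted two-group simulation is recovered at high precision", {
  cfg <- simulationConfig(n_genes = 2000L, n_de_genes = 100L, de_log2fc = 3,
                          seed = 11L)
  ex <- simulateExpression(cfg, seed = 11L)
  em <- ex$matrix
  a <- colnames(em)[grepl("^tolerant_normal", colnames(em))]
  b <- colnames(em)[grepl("^sensitive_normal", colnames(em))]
  deg <- callDegs(em, a, b)
  calls <- deg$gene_id[deg$significant]
  truthDE <- ex$truth$gene_id[ex$truth$de]
  recall <- mean(truthDE %in% calls)
  fdp <- if (length(calls)) mean(!(calls %in% truthDE)) else 0
  expect_gte(recall, 0.8)
  expect_lte(fdp, 0.05)
  ## directions match the planted signs
  planted <- deg[deg$significant & deg$gene_id %in% truthDE, ]
  signs <- ex$truth$log2fc[match(planted$gene_id, ex$truth$gene_id)]
  expect_true(all(planted$direction == ifelse(signs > 0, "up", "down")))
})

test_that("fold-change bins are right-closed with exact boundary handling", {
  s <- summarizeFoldBins(degTable(sprintf("g%d", 1:4),
                                  c(1500, 500, 50, 3),
                                  rep("up", 4)))
  expect_equal(unname(s$bins[, "up"]), c(1L, 1L, 1L, 1L))
  expect_equal(s$up_total, 4L)
  expect_equal(s$down_total, 0L)
  ## FC = 10 exactly falls in the 2-10 bin; 1000 in 100-1000
  s2 <- summarizeFoldBins(degTable(c("a", "b"), c(10, 1000),
                                   c("up", "down")))
  expect_equal(s2$bins["2-10", "up"], 1L)
  expect_equal(s2$bins["100-1000", "down"], 1L)
  ## a significant record at FC <= 2 is a consistency error
  expect_error(summarizeFoldBins(degTable("bad", 1.5, "up")), "inconsistent")
})

test_that("bin summaries conserve the significant record count", {
  set.seed(44)
  fc <- exp(runif(300, log(2.001), log(5000)))
  dir <- sample(c("up", "down"), 300, replace = TRUE)
  s <- summarizeFoldBins(degTable(sprintf("g%d", 1:300), fc, dir))
  expect_equal(s$total, 300L)
  expect_equal(s$up_total + s$down_total, 300L)
  expect_equal(sum(s$bins), 300L)
})
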