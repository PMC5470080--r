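## Independent reference implementations ("oracles") shared by the unit
## and acceptance tests.  These deliberately avoid the package's code
## paths: quadrature and direct-space Beta functions for the linkage
## marginals, term-by-term log-gamma summation for the tag test, a
## quadratic step-up rule for BH, and a literal transcription of the
## site-validation rules.

quadMarginal <- function(a, b) {
  stats::integrate(function(p) p^a * (1 - p)^b, 0, 1,
                   rel.tol = 1e-13, abs.tol = 0)$value
}

quadPosterior <- function(aT, bT, aS, bS, pi = 0.05) {
  L1 <- quadMarginal(aT, bT) * quadMarginal(aS, bS)
  L0 <- quadMarginal(aT + aS, bT + bS)
  pi * L1 / (pi * L1 + (1 - pi) * L0)
}

## direct-space (non-log) Beta-function posterior, vectorised
betaPosterior <- function(aT, bT, aS, bS, pi = 0.05) {
  L1 <- beta(aT + 1, bT + 1) * beta(aS + 1, bS + 1)
  L0 <- beta(aT + aS + 1, bT + bS + 1)
  pi * L1 / (pi * L1 + (1 - pi) * L0)
}

## predictive pmf p(y | x) by explicit log-gamma summation
oraclePredictive <- function(y, x, n1, n2) {
  r <- n2 / n1
  exp(y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
        (x + y + 1) * log1p(r))
}

oracleLowerTail <- function(y, x, n1, n2) {
  sum(oraclePredictive(0:y, x, n1, n2))
}

## naive O(n^2) BH step-up
naiveBH <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    ri <- which(o == i)
    cand <- vapply(ri:n, function(j) p[o[j]] * n / j, numeric(1))
    q[i] <- min(1, min(cand))
  }
  q
}

## literal site-validation reference: qualifying types need >= 3 reads and
## >= 20% of the pooled total; pass iff exactly two qualify and together
## hold >= 90%; otherwise label by the stated precedence, with the
## runner-up type deciding low_type_support vs monomorphic.
naiveClassify <- function(v, minReads = 3, minFrac = 0.2, twoFrac = 0.9) {
  v <- v[v > 0]
  tot <- sum(v)
  v <- v[order(-v, names(v))]
  qualifies <- logical(length(v))
  for (i in seq_along(v))
    qualifies[i] <- (v[i] >= minReads) && (v[i] / tot >= minFrac)
  nq <- sum(qualifies)
  if (nq == 2) {
    if (sum(v[qualifies]) / tot >= twoFrac)
      return(list(pass = TRUE, types = names(v)[qualifies],
                  reason = "pass"))
    return(list(pass = FALSE, reason = "low_combined_fraction"))
  }
  if (nq >= 3) return(list(pass = FALSE, reason = "too_many_types"))
  if (length(v) >= 2 && v[2] < minReads)
    return(list(pass = FALSE, reason = "low_type_support"))
  list(pass = FALSE, reason = "monomorphic")
}
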