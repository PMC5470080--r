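---
title: "Methods: two-pool BSR-seq linkage and expression analysis"
author: "bsrseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-pool BSR-seq linkage and expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsrseq)
```

# The design this package analyses

Bulked segregant RNA-seq (BSR-seq) sequences the RNA of two pools of
individuals chosen for opposite phenotypes — here a *tolerant* bulk pooled
from 8 inbred lines and a *sensitive* bulk pooled from 10, each sequenced
under two conditions (untreated and stressed) with three biological
replicates.  One experiment yields two complementary signals:

* **allele-frequency divergence between the bulks** at SNP sites, which
  points to loci genetically linked to the phenotype, and
* **differential expression** between pools and between conditions, which
  points to genes transcriptionally involved in the response.

`bsrseq` implements the computational footprint of such a study: site
validation on pooled allele depths, a Bayesian linkage probability per
SNP, cross-condition intersection of high-probability SNPs, digital-tag
differential-expression calls, and the integration of both signals into a
ranked candidate-gene table.  A seeded generator reproduces the whole
design with ground truth so every stage can be tested for recovery and
calibration.

# SNP-site validation

Reads covering a site are typed by base.  A *valid* SNP site must carry
**two and only two** supported SNP-types: a type qualifies when it has at
least `min_type_reads = 3` reads **and** at least `min_type_fraction =
20%` of the pooled site total, and the two qualifying types must jointly
hold at least `min_two_type_fraction = 90%` of that total.  All three
thresholds are inclusive.  Counts are pooled across both bulks and both
conditions before typing, because the linkage model downstream needs the
same two alleles oriented consistently in both bulks; typing within a
single condition is available through `filterSites(..., condition =)`.

Failure labels are mutually exclusive.  With exactly two qualifying types
but insufficient combined mass the site is `low_combined_fraction`; three
or more qualifying types is `too_many_types`.  With fewer than two, the
runner-up type decides: if the second-largest observed type fails the
minimum-read rule the site is `low_type_support` (deeper sequencing could
rescue it), otherwise — when it fails only the fraction rule, or no second
type exists — the site is `monomorphic`.  Tolerating residual noise types
inside the 10% remainder is deliberate: requiring literally no third base
would discard a real SNP for a single miscalled read.

# The linkage-probability model

The study design implies that at a SNP linked to the causal locus the two
bulks have different allele frequencies, while at an unlinked SNP they
need not sit at any particular value — pools of unrelated inbreds are not
an F2, so the null is *one shared frequency*, not ½.  For a validated site
with counts $(a_T, b_T)$ and $(a_S, b_S)$ of the two retained alleles:

* $H_1$ (linked): each bulk has its own frequency with independent
  $\mathrm{Beta}(\alpha_1, \beta_1)$ priors, so
  $L_1 = m(a_T, b_T)\, m(a_S, b_S)$;
* $H_0$ (unlinked): one shared frequency with a
  $\mathrm{Beta}(\alpha_0, \beta_0)$ prior, so
  $L_0 = m(a_T + a_S,\; b_T + b_S)$,

where $m(a,b) = B(a+\alpha, b+\beta)/B(\alpha, \beta)$ is the
beta-binomial marginal with the binomial coefficient omitted (it is
common to both hypotheses and cancels).  The posterior is

$$P(\text{linked} \mid \text{counts}) =
  \frac{\pi L_1}{\pi L_1 + (1-\pi) L_0},$$

computed in log space throughout.  Defaults are uniform priors
$\alpha = \beta = 1$ and $\pi = 0.05$ — small prior mass, since a single
causal region is expected in a genome-wide scan.  A `null_mode = "half"`
switch scores the pooled counts against a fixed frequency of ½ instead.
SNPs are *called* when the posterior strictly exceeds 0.9, and the
per-condition call sets are intersected by (chromosome, position,
unordered allele pair): a genuine linkage signal reflects genotype, which
both conditions share, so it should replicate across them.

The prior $\pi$ can instead be estimated from the data
(`em_enabled = TRUE`): treating the sites as a two-component mixture, the
E-step computes per-site posteriors at the current $\pi$ and the M-step
replaces $\pi$ by their mean, iterating to `em_tol = 1e-6` (at most 100
iterations, estimate clamped to $[10^{-6}, 0.5]$).  The mixture
log-likelihood is non-decreasing across iterations and is checked in the
tests; on data generated from the model with 10% linked sites at depth
200 the estimate lands within ±0.05 of 0.10.

## What the posterior does and does not measure

The statistic detects *any* true difference between the bulk allele
frequencies.  In bulks pooled from only 8 and 10 lines, unlinked sites
have genuinely different carrier fractions whenever the binomial lattice
draws diverge (e.g. 7/8 against 5/10), and at depth ~50 per bulk such
sites are correctly, from the model's point of view, assigned high
posteriors.  Under the default simulation about 16–17% of
off-chromosome SNPs exceed the 0.9 threshold for exactly this reason —
a property of the design (small pools), not a numerical artifact.
Requiring a SNP to replicate across both conditions roughly halves that
rate; larger pools or a null that models the finite-pool lattice would
reduce it further, at the cost of leaving the simple shared-frequency
model this package deliberately fixes.

# Digital expression

Expression is normalised as RPKM,
$10^9 \, C / (N L)$ for count $C$, library size $N$ (reads) and gene
length $L$ (bp).  Differential expression between two sides is tested on
*pooled* tag counts: replicate counts are summed into one library per
side (`pool_sum`), because the two-library tag test is defined for a pair
of libraries, not a replicated design.  This discards biological
replicate dispersion — a documented limitation; it matches designs whose
replicates are re-sequencings of the same pooled RNA.

Given count $x$ in a library of size $N_1$, the null predictive
distribution of the count $y$ in a library of size $N_2$ is

$$p(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!\,(1 + N_2/N_1)^{x+y+1}},$$

which is a negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$; tails are evaluated through that identity, in log space.
The two-sided p-value doubles the smaller of the lower tail
$P(Y \le y)$ and the strict upper tail $P(Y > y)$, capped at 1 — this
equal-tail form is symmetric in the two libraries,
`acTest(x, y, n1, n2) == acTest(y, x, n2, n1)`, so the result does not
depend on which side is called "first".  Genes with zero pooled counts on
both sides are excluded from testing; p-values are BH-adjusted across the
tested genes.

A gene is a significant DEG when its fold change strictly exceeds 2 and
its FDR is at most 0.001.  The fold change is the ratio of pseudocounted
mean RPKMs, $(\bar R_A + 0.01)/(\bar R_B + 0.01)$, reported as a value
$\ge 1$ with the direction carried separately; the 0.01 pseudocount lets
a gene silent on one side still yield a finite — possibly >1000-fold —
ratio.  Significant calls are binned by magnitude into right-closed
classes $(2,10]$, $(10,100]$, $(100,1000]$, $(1000,\infty)$: a fold
change of exactly 10 belongs to the 2–10 class, consistent with
"greater than two-fold" being an open bound at 2.

# Candidate integration

Two between-pool contrasts (one per condition) are overlapped by gene id;
each shared gene is classed `concordant` or opposite (`down_then_up` /
`up_then_down`) by its direction pair, and the classes partition the
overlap.  Every gene containing at least one cross-condition
high-probability SNP enters the candidate table exactly once, annotated
with its DEG status per contrast, and is ranked by (number of contrasts
significant, maximum SNP posterior, SNP count), ties broken by gene id.
Marker intervals are plain coordinate queries (`genesInRegion`), 1-based
inclusive, a single shared base pair counts.

# The synthetic generator

The generator reproduces the study conditions, not a generic population:

* **Panel**: 8 tolerant and 10 sensitive inbred lines.  Every tolerant
  line carries the tolerant allele at one causal locus, every sensitive
  line the alternative.  At a SNP at distance $d$ on the causal
  chromosome a line carries the causal-coupled allele with probability
  $c(d) = 0.5 + 0.5 e^{-d/L}$ given its causal allele; on other
  chromosomes $c = 0.5$.  Bulk frequencies are carrier fractions, so they
  live on the $k/8$ and $k/10$ lattices.  The decay scale defaults to
  $L = 10$ Mb: an LD-style stand-in for the broad linkage block a bulked
  design produces around a causal locus, chosen so that a 2,000-SNP scan
  contains a few dozen strongly coupled ($c \ge 0.95$) sites.  Kilobase-
  scale panel LD would be realistic for an association panel but would
  leave essentially no partially coupled SNPs at this marker density, and
  it is the linkage block, not panel LD, that the analysis consumes.
* **Allele depths**: per bulk-condition cell, depth is
  Poisson(`mean_depth` = 50); reads of the focal allele are binomial with
  probability $f(1-\varepsilon) + (1-f)\varepsilon$
  ($\varepsilon$ = 0.01), and each remaining read is miscalled to one of
  the two other bases with probability $\varepsilon/2$ apiece — the only
  mechanism that can violate the two-type site rule.  Both conditions
  share genotypes and differ only in sampling noise, which is what makes
  the cross-condition SNP intersection meaningful.
* **Expression**: three replicates per bulk-condition cell; baseline
  per-replicate expected counts log-uniform over three decades (1–1000
  reads, a typical RNA-seq dynamic range); `n_de_genes = 100` genes get a
  $2^{\pm 3}$ multiplier in the tolerant bulk (sign random), emulating
  constitutively pool-divergent genes.  Counts are negative binomial with
  dispersion 0.01, scaled to log-normal library sizes around 2 million
  reads.  The small dispersion reflects replicates that are pools of the
  same 8–10 lines: pooling averages line-to-line biological variance, and
  the residual spread is close to technical.  Larger dispersions would
  also make the pooled-count tag test anticonservative (its null is
  Poisson), which is the documented cost of the `pool_sum` design.
* **Gene models**: uniform placement, lengths uniform in 500–5000 bp;
  the first gene is always centred on the causal locus so the causal SNP
  is genic (`gene0001`).

What the generator does **not** emulate: read-level artifacts (mapping
bias, duplicates), indels and multi-allelic sites, population structure
beyond the two bulks, LD among non-causal SNPs, and genuinely
overdispersed biological replicates.  Passing recovery tests on this
generator therefore demonstrates correctness of the inference machinery
under its stated model, not robustness to those real-data features.

# Numerical and interface choices

* All likelihoods in log space; `lbeta`/`lgamma` throughout; posteriors
  via `plogis(qlogis(pi) + logBF)` so extreme Bayes factors cannot
  overflow.  Tag-test tails use `pnbinom` with `lower.tail = FALSE` for
  the upper tail to avoid cancellation at extreme counts.
* Sorting of calls is by (chromosome lexicographic, position ascending);
  candidate ranking breaks ties by gene id, so every output is
  deterministic.
* Coordinates are 1-based inclusive everywhere a user sees them
  (GFF3/VCF convention, carried by `GRanges`); strand is preserved but
  ignored for SNP-in-gene assignment.
* Read QC discards a read only when a threshold is *exceeded* (strictly
  more than 5% N, or strictly more than 20% of bases at Q ≤ 10); the
  filter is applied per read, with phred+33 assumed by default and
  phred+64 available.  A read failing both rules is counted once, under
  the N rule, so QC summaries partition their input.
* Problem sizes used by the test-suite recovery runs — 2,000 SNPs at
  depth 50, 2,000 genes × 12 samples, 1,000-site EM mixtures, and a
  400-SNP/300-gene configuration for the byte-identity reruns — are the
  package's reference configurations; they are large enough that every
  empirical rate asserted in the tests is stable to reseeding at the
  asserted tolerance.
* `runPipeline()` is the single orchestration entry point; it seeds every
  stage from one integer, records every parameter and output digest in a
  JSON manifest, and reruns byte-identically.

# Known limitations

* The pooled tag test ignores replicate dispersion; with strongly
  overdispersed replicates its raw FDR is optimistic and only the
  fold-change gate keeps null calls rare.  A count-model alternative
  (e.g. a negative-binomial GLM) is out of scope by design.
* The shared-frequency null does not model the finite-pool lattice, so
  with 8/10-line bulks a material fraction of unlinked sites is *truly*
  frequency-divergent and scores as linked; see the discussion above.
* Multi-allelic truth, indels and QTL-seq-style index statistics are not
  implemented.
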