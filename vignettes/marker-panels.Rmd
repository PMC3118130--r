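---
title: "Selecting informative SNP panels for population assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting informative SNP panels for population assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpanel)
library(dplyr)
```

## The problem

High-density SNP chips genotype tens of thousands of loci, but routine
breed verification, traceability or provenance testing needs a panel of at
most a few hundred markers. Given reference allele frequencies for K
candidate populations, the task is (i) to score every locus for how well its
frequencies discriminate the populations, (ii) to rank loci and build panels
cumulatively from the top, (iii) to assign query genotypes by likelihood
and measure success at several confidence tiers, and (iv) to estimate the
smallest panel achieving a target success rate. `snpanel` implements each
stage as a tibble-in/tibble-out function so the stages compose with the
pipe, and ships a multi-breed genotype simulator so the whole pipeline can
be exercised and tested without external data.

## The assignment model

A diploid genotype at a biallelic locus with reference-allele dosage
g ∈ {0, 1, 2} has Hardy–Weinberg probability (1−p)², 2p(1−p) or p² under a
population whose reference-allele frequency is p. Loci are treated as
independent, so the multilocus log-likelihood is the sum of per-locus terms;
all logs are base 10. Two numerical details matter:

* **Frequency clamping.** Observed frequencies of exactly 0 or 1 would give
  impossible genotypes infinite penalty. They are replaced by 1e−5 and
  0.99999 (configurable in `assignment_config()`) immediately before
  likelihood computation; stored panels keep raw frequencies. A locus fixed
  for opposite alleles in two populations therefore contributes
  2·log10(0.99999/1e−5) ≈ 10 units of log-likelihood ratio per genotype.
* **Stringency.** The LLR compares the known origin against the *best
  non-origin* population. An individual passes threshold t when LLR > t
  strictly; otherwise it is assigned to the maximum-likelihood population.
  Thresholds 0–3 demand the origin be 1/10/100/1000 times more likely than
  any alternative. Ties in the argmax are broken by population identifier
  and reported; an LLR exactly equal to the threshold fails it. Missing
  genotypes contribute a likelihood factor of 1, which keeps likelihoods
  comparable across populations within an individual but not across
  individuals with different call rates — a documented caveat, not a
  correction.

## Informativeness measures

`delta_informativeness()` averages |p_i − p_j| over all population pairs.
`wright_fst()` computes var(p)/(p̄(1−p̄)) with the population
(divide-by-K) variance and unweighted mean — chosen so that the two-
population fixation case scores exactly 1 — either once over all K
(`global`) or averaged over pairs (`pairwise`); a locus monomorphic in every
population is a 0/0 case and scores 0. `wc_fst()` is the variance-components
moment estimator computed from sample frequencies and per-population sample
sizes; it corrects finite-sample noise, may legitimately go negative (no
differentiation), and keeps those negative values because truncation would
distort the low tail of the ranking. The heterozygote-correction terms of
the full 1984 formulation are not used: the estimator works from allele
frequencies alone, as is standard when individual-level heterozygosity is
unavailable.

`pca_informativeness()` performs PCA on the population × locus frequency
matrix, centring each locus and *not* scaling it (unit-variance scaling
would inflate low-MAF loci). Component significance is decided against a
permutation null: each of `n_random_matrices` (default 100) randomized
panels resamples every locus's K values with replacement across populations,
destroying population structure while preserving each locus's marginal
spectrum. A component rank is significant when the real eigenvalue exceeds
the 0.95 quantile of the null eigenvalues of the same rank; the quantile is
configurable because "greater than the randomized eigenvalues" admits both a
maximum and a quantile reading, and the number of significant components is
reported with the result. The score is the sum of squared loadings over
significant components. Row and column order of the input never affect the
result (rows and columns are canonicalised internally before the
decomposition and the permutation draws).

Rankings (`rank_markers()`) order loci by decreasing score with ties broken
by locus identifier in the C locale — an arbitrary but reproducible total
order. `compare_rankings()` reports the Spearman correlation of score
vectors (average ranks on ties) and the top-n overlap.

## Panel-size estimation

`cumulative_assignment()` traces success against panel size on a grid
(default every 20 markers up to 400, both configurable, matching common
practice for reduced-panel design). `fit_assignment_curve()` fits the
asymptotic regression y = a + b·exp(cx) by Levenberg–Marquardt least
squares, unweighted across grid points, starting from a₀ = max(y),
c₀ = −0.01, b₀ = y(first) − a₀; with a > 0, b < 0, c < 0 this is the law of
diminishing returns, a being the asymptotic success. `invert_curve()`
returns x\* = ln((y\*−a)/b)/c, a deliberately fractional marker count; a
target at or above the asymptote raises an explicit "asymptote below
target" error rather than extrapolating. Constant curves (no information on
the rate parameter) are refused.

`random_panel_control()` repeats the curve on uniformly drawn marker sets
(default 20 sets of 400) and averages them — the negative control showing
what ranking buys. `cross_validate()` removes a holdout per population
(all designated queries for reference sizes above 50, otherwise 5 random
individuals), re-estimates the reference frequencies *and re-ranks the
markers* on the training individuals only, then assigns the holdouts. Re-
ranking is the default because reusing a ranking that saw the holdouts
leaks selection information; a precomputed ranking can be passed explicitly
when the leak is intended for comparison.

## The simulator

`simulate_panel()` draws each locus's ancestral frequency uniformly from
(0.05, 0.5) (assigned to either allele at random), then per-breed
frequencies from the Balding–Nichols Beta distribution with divergence
parameter F — chosen because its parameter *is* the fixation index the
estimators target, which enables parameter-recovery tests. Genotypes are
Binomial(2, p) dosages; the emitted panel holds the *sample* frequencies
recomputed from those genotypes, so panel and cohort carry mutually
consistent sampling noise. Chip-like ascertainment is a pooled-MAF filter
(default 0.05): failing loci are redrawn until the requested count passes,
with a bounded attempt budget so an unsatisfiable filter fails loudly.
Recently split breed pairs (e.g. two herd-books of the same ancestral
breed) are modelled as a two-level hierarchy — a pair-ancestor at the
breed-level F, members around it at F = 0.01. Missingness is optional
missing-completely-at-random. Every locus draws from its own seeded
substream, so enlarging a simulation leaves earlier loci bit-identical.

What the simulator does *not* emulate: linkage disequilibrium (loci are
exchangeable and independent), mutation or selection, pedigree structure
within breeds, and the discovery-panel ascertainment that shapes real chip
spectra beyond a MAF floor. Passing tests therefore demonstrate the
correctness and the qualitative behaviour of the pipeline — estimator
recovery, ranking agreement, stringency monotonicity, the cost of
cross-validation — not field performance on any particular livestock
dataset.

## Study conditions used by the tests and the acceptance script

The standard cohort is 8 breeds at F = 0.10 with 30 diploids each and 5000
filtered loci — large enough that across-locus means are stable (the
Monte-Carlo standard error of the mean per-locus Weir–Cockerham estimate is
below 0.001) while the full suite runs in about a minute. Under these
conditions the mean *per-locus* global Weir–Cockerham estimate sits near
0.082, noticeably below the generative F = 0.10: the per-locus ratio
estimator is Jensen-biased downward at K = 8, while the ratio-of-sums
multilocus estimator would be nearly unbiased. Similarly, at F → 0 the mean
per-locus pairwise estimate converges to −1/(2N−1), not 0 — sampling noise
alone drives it slightly negative. Both facts were established with an
independent large-L Monte-Carlo oracle before the tests froze them.

Two further behaviours deserve note. First, resubstitution (assigning
individuals against frequencies they contributed to) inflates success
markedly — with 25 individuals per breed and 400 noise loci at F ≈ 0 it
reaches ~97% where chance is 25% — which is why chance-level behaviour is
asserted on held-out individuals and why the cross-validation module exists.
Second, ranked and random curves both saturate at exactly 100% on well-
differentiated simulated cohorts, so "the ranked curve dominates the random
control" is asserted as weak dominance: never worse at any grid point and
strictly better at at least one.

The cross-validation experiment uses 10 replicates of a 6-breed cohort
(sizes 48/30/25/20/15/12, 1500 loci) containing one recently split pair at
within-pair F = 0.01 — emulating the situation where a small breed has a
near-indistinguishable larger relative in the reference set. The holdout
rule and the re-ranking default make the related small breeds degrade most,
which the tests assert.

One open question in the protocol is whether query individuals should
contribute to the reference frequencies at all. The simulator emits a
resubstitution panel (they do), because that matches how reference panels
are typically built from all available genotypes; `cross_validate()` makes
the exclusion explicit when the unbiased estimate is wanted.

## Known limitations

* Locus independence is assumed by the likelihood; panels assembled from a
  chip with strong local LD will overstate confidence.
* The clamping constants bound the contribution of any single locus; the
  default ±5 orders of magnitude follows common practice, and conclusions
  near a stringency boundary can in principle depend on them.
* The asymptotic regression is a summary, not a mechanistic model; its
  inverted panel sizes are interpolations on the fitted curve and become
  extrapolations (refused) when the target exceeds the asymptote.
* Per-breed success on small holdouts is quantised (5 individuals ⇒ 20%
  steps), so cross-validated per-breed curves are coarse by construction.
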