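---
title: "Genotype reconstruction in multiparent populations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype reconstruction in multiparent populations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mpphmm)
```

## The reconstruction problem

An individual from a multiparent population (MPP) carries chromosomes that
are mosaics of its founder strains' haplotypes. Given dense biallelic SNP
calls on the individual and on the (inbred, hence haploid-equivalent)
founders, genotype reconstruction assigns to every position the posterior
probability of each possible founder origin. `mpphmm` implements a hidden
Markov model (HMM) whose hidden states are founder genotypes, whose
transition kernel derives from a generic breeding abstraction, and whose
emissions tolerate genotyping error.

## The random-mating abstraction

Rather than modelling each breeding design exactly, the population is
idealised as `k` inbred founders in proportions $\alpha_1,\dots,\alpha_k$
followed by $n$ discrete generations of random mating among a very large
set of mating pairs. For two loci at recombination fraction $r$, the
probability that a random haplotype carries founder alleles $i$ and $j$
obeys

$$p_{ij}(n) = (1-r)\,p_{ij}(n-1) + r\,\alpha_i\alpha_j,
\qquad p_{ij}(0)=\alpha_i\,[i=j],$$

because a generation-$n$ haplotype is either an intact copy of a
generation-$(n-1)$ haplotype (probability $1-r$) or a recombinant joining
two independently drawn alleles. The closed form is

$$p_{ii}(n)=\alpha_i^2+(1-r)^n\alpha_i(1-\alpha_i),\qquad
p_{ij}(n)=\alpha_i\alpha_j\bigl[1-(1-r)^n\bigr]\ (i\neq j),$$

implemented in `twoPointProbs()`; the recursion (`twoPointRecursion()`,
integer $n$ only) is retained purely as a brute-force test oracle, and the
suite verifies agreement to $10^{-12}$. Dividing by the marginal
$\alpha_i$ gives the haplotype transition kernel
(`haplotypeTransition()`), which is stochastic and $\alpha$-stationary.

**Phase.** Homozygous populations (RIL, MAGIC) are doubled haploids: the
chain over the $k$ homozygous states is exactly the haplotype chain.
Heterozygous populations (AIL, DO, HS) carry two independent haplotypes;
`genotypeTransition()` forms the ordered product chain over $k^2$ pairs
and collapses it to the $k(k+1)/2$ unordered states, since SNP data cannot
distinguish phase. The ordered chain is kept behind `ordered = TRUE` for
debugging, and a direct unordered formula serves as the independent oracle
in the tests.

**X chromosome.** The same formulas are used with $n$ replaced by
$(2/3)n$, because recombination happens only in females and two-thirds of
X chromosomes reside in females. This makes non-integer $n$ routine, which
is why every user-facing computation goes through the closed form. In
heterozygous populations, males on the X are a hemizygous $k$-state chain;
observed heterozygous male-X calls are set missing with a warning (they
are almost certainly genotyping artifacts). The initial X distribution is
kept at $\alpha$; exact design-specific models (e.g. the CC funnel) can
concentrate or exclude founders on the X, which the generic model cannot
express — a known, accepted approximation.

## Calibrating the effective number of generations

Let $R(r)=1-\sum_i p_{ii}(n)$ be the chance a random haplotype carries
different founder alleles across an interval — the exchange probability,
$(1-\sum_i\alpha_i^2)(1-(1-r)^n)$ here. Its slope at $r=0$ is the *map
expansion* $n(1-\sum_i\alpha_i^2)$, i.e. the population's breakpoint
density relative to one meiosis. Matching a design's known map expansion
fixes $n$ (`calibrateNClosedForm()`):

* **CC:** the exact eight-way sib-mating result $R(r)=7r/(1+6r)$ has slope
  7, and $7/(7/8)=8$, so $n=8$.
* **DO:** the autosomal map expansion at outbreeding generation $s$ is
  approximately $(7s+37)/8$; equating with $(7/8)n$ gives $n=s+37/7$,
  whose offset from $s$ rounds to $+5$ for every $s$.

These reference formulas live in `ccExchangeProbability()`,
`doMapExpansion()`, `doEffectiveN()`. The CC funnel X bookkeeping
(`ccFunnelXProbs()`) enumerates transmission generically: daughters
receive a random maternal X plus the paternal X, sons a random maternal X,
and sib-mating fixes each of the final pair's three X copies with
probability 1/3; for any funnel this yields probabilities 1/6, 1/6, 1/3,
0, 1/6, 1/6, 0, 0 over funnel positions 1–8, with the mitochondria from
position 1 and the Y from position 8.

## The HMM

* **States** (`stateSpace()`): founders (haploid/homozygous/male X) or
  unordered founder pairs, homozygotes first then pairs lexicographically;
  founders with $\alpha_i=0$ are kept but flagged unreachable so one
  indexing serves every individual.
* **Initial distribution** (`initialDistribution()`): $\alpha$ or its
  Hardy–Weinberg products — the chain's stationary law.
* **Emissions** (`emissionMatrix()`): state $(i,j)$ predicts dosage
  $f_{mi}+f_{mj}$ from the founder allele matrix; a matching observation
  scores $1-\varepsilon$, a mismatch $\varepsilon/2$ (the error mass split
  over the two wrong dosage categories — a modelling choice, configurable
  through the error rate only), and a missing observation or founder
  allele scores 1. Monomorphic markers thus stay in the model as
  uninformative positions, preserving indexing. Default
  $\varepsilon = 0.002$, the conventional SNP-array error rate for these
  data.
* **Forward–backward** (`forwardBackward()`): per-position scaling rather
  than log-space arithmetic (fewer transcendental calls on state spaces of
  at most a few dozen states); scaling constants are summed in log to
  return the log-likelihood, and posterior rows are renormalised to
  control drift. A position where no state can emit the observation (only
  possible at $\varepsilon = 0$) raises an error naming the position.
* **Viterbi** (`viterbiPath()`): log-space maximisation with deterministic
  ties to the lowest state index.
* **Segments** (`inferSegments()`): positions whose maximum posterior
  reaches the threshold (default 0.95, above 0.5 by construction) are
  assigned; runs of one state form segments, unassigned stretches carry no
  state and do not split a run, and breakpoints are state changes between
  consecutive assigned segments.

`reconstruct()` orchestrates all of this per individual and chromosome,
reconciling the marker universes of founder file, offspring file and map
by intersection (array data routinely mismatch; dropped markers are
reported, order follows the map), optionally inserting pseudomarkers on a
grid anchored at each chromosome's first marker.

## Map functions and numerical choices

Genetic distance converts to recombination fraction under Haldane,
Kosambi or Carter–Falconer (`mapDistanceToRecFrac()`); the HMM itself is
interference-free, so the map function is exposed as a user choice
(default Carter–Falconer, the convention for mouse array data). The
Carter–Falconer forward direction has no closed form and is computed by
bracketed root-finding to $10^{-12}$. Coincident marker positions are
perturbed by $10^{-6}$ cM increments in input order, making interval
recombination fractions well-defined ($r \ge 0$) and ordering
deterministic.

## The simulator

`simulatePopulation()` performs the breeding abstraction literally:
founder generation drawn from $\alpha$, then $n$ rounds in which each
offspring takes one gamete from each of two distinct parents sampled
uniformly (selfing excluded) from a population of `2 * popPairs`
individuals. Meiosis (`simulateMeiosis()`) is interference-free — Poisson
crossovers at one per Morgan, uniform positions, fair-coin start —
because the transition model itself assumes only per-interval
recombination fractions; crossovers between identical-founder homologs
are silent and are merged, matching the definition of $R(r)$ as an
exchange of *alleles*. The default of 500 mating pairs (1000 haplotypes)
approximates the "very large population" assumption; substantially
smaller populations acquire measurable coancestry, which inflates
two-locus founder identity above the infinite-population closed form, so
validation runs use replicate populations and replicate-level standard
errors. Genotypes are attached by reading dosages off the mosaics, with
each call corrupted with probability $\varepsilon$ to a uniformly chosen
different category; founder alleles are drawn per marker with a
Beta-distributed coded-allele frequency, redrawing most monomorphic
markers.

`estimateMapExpansion()` counts breakpoints per haplotype per Morgan, and
`calibrateNBySimulation()` returns the smallest integer $n$ whose
simulated expansion's $\pm 3$ SE interval covers (or first exceeds) the
target, reporting the closed form alongside.

## What the synthetic data do and do not show

The simulator reproduces the model's own assumptions (random mating, no
interference, uniform error) plus finite-population effects the closed
form ignores. Passing reconstruction tests therefore demonstrate correct
inference *under the model*, not robustness to crossover interference,
marker-specific error rates, segregation distortion or founder
mis-specification in real arrays. One limit worth stating plainly: a true
founder segment that spans no marker distinguishing it from its
neighbours — common for segments under ~0.5 cM at 0.1 cM marker spacing,
since two founders share an allele at roughly half the markers — is
invisible to any reconstruction method, so per-haplotype breakpoint counts
are recovered only up to such undetectable segments; breakpoint *density*
(the quantity the $n$ calibration controls) is recovered accurately.

## Problem sizes and defaults

Validation runs in the test suite use desk-scale sizes chosen to make the
statistics decisive: 100 random draws for closed-form/recursion identity,
exhaustive path enumeration up to 4 positions × 6 states, populations of
500 pairs (1000 haplotypes, 100 cM) for breakpoint density and two-locus
frequencies, and 10 homozygous individuals at 1000 markers/100 cM for
end-to-end recovery (accuracy bar 95% at threshold 0.95). Defaults
throughout: $\varepsilon = 0.002$, threshold 0.95, Carter–Falconer map
function, equal founder proportions, 500 mating pairs, seed recorded in
every run log.
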