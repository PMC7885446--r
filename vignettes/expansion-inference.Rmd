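---
title: "Detecting and dating sudden demographic expansions from mtDNA mismatch distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and dating sudden demographic expansions from mtDNA mismatch distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molexpand)
```

## The problem

Late-Quaternary climate cycles repeatedly compressed and released the ranges
of small terrestrial mammals. A population that expands suddenly from a small
refugium leaves a characteristic signature in its mitochondrial sequences:
a star-shaped haplotype genealogy, an excess of rare variants (negative
Tajima's D, strongly negative Fu's Fs), and a smooth unimodal *mismatch
distribution* — the histogram of pairwise nucleotide differences between
sampled sequences. `molexpand` implements the full inferential chain for
aligned mtDNA haplotypes (the motivating system is the 1140-bp cytochrome
*b* gene of Japanese moles, sampled per haplogroup at n = 14–36): diversity
summaries and neutrality tests, least-squares fitting of the
sudden-expansion model with a parametric bootstrap, median-joining networks,
and the conversion of expansion ages to calendar time and substitution rates
against biogeographic calibration points.

## The sudden-expansion model

All times are *mutational*: with u the per-sequence per-generation mutation
rate and N the (female effective) population size, θ = 2Nu and an event t
generations ago sits at τ = 2ut mutational units. A stationary population
has a geometric mismatch distribution,

$$\hat F_d(\theta) = \frac{\theta^d}{(\theta+1)^{d+1}},$$

implemented by `equilibrium_mismatch()`. If the parameter jumped
instantaneously from θ₀ to θ₁ at time τ before the present, the transient
distribution is

$$F_d(\tau,\theta_0,\theta_1) = \hat F_d(\theta_1) +
  e^{-\tau(\theta_1+1)/\theta_1}\sum_{i=0}^{d}\frac{\tau^i}{i!}
  \left[\hat F_{d-i}(\theta_0) - \hat F_{d-i}(\theta_1)\right],$$

implemented by `expected_mismatch()`. Three limits pin the formula down and
are unit-tested: τ = 0 returns the θ₀ equilibrium; τ → ∞ the θ₁ equilibrium;
and θ₀ = 0 with θ₁ → ∞ the Poisson(τ) distribution, so that the mean of the
compound case is τ + θ₀. The same formula is checked against the package's
own coalescent simulator: the pooled mismatch distribution of 2000
simulated samples (n = 50) at (τ = 4, θ₀ = 1, θ₁ = 100) agrees with the
closed form to a total variation distance well under 0.03.

```{r closed-form}
round(expected_mismatch(3, 1, 1000, d_max = 8), 4)
```

## The coalescent simulator

`demography()` + `simulate()` draw samples from the n-coalescent with a
piecewise-constant population size. Time is scaled so that a pair of
lineages in the *current* population coalesces at rate 1 while mutations
fall on each lineage at rate θ₁/2 per unit; the backward size change
θ₁ → θ₀ then occurs at time τ/θ₁. This is the scaling under which a
non-coalescing pair accumulates exactly τ differences on average since the
expansion — the property that makes the simulator and the closed form
speak the same parameter language, and it is tested through the Poisson
limit above. θ₀ = 0 produces a star genealogy (all lineages coalesce at
the boundary). Mutations are infinite-sites by default (each hit is a new
column when exported to an alignment, mapped onto k = 1140 positions
without collision); a finite-sites Jukes–Cantor export is available for
data with recurrent substitution, which matters little at the shallow
divergences this model targets. `fixed_s_null()` instead conditions on the
number of segregating sites, placing exactly S mutations on branches with
probability proportional to branch length.

Every simulation entry point takes a master seed; per-replicate seeds are
derived deterministically (seed + replicate index), so panels are
reproducible and replicate i does not depend on how many replicates were
requested.

What the generator deliberately does *not* emulate: recombination (absent
in mtDNA), migration and population structure, selection, sequencing
error, and rate heterogeneity across sites. A passing test suite therefore
demonstrates correctness of the inferential machinery under the model's
own assumptions, not robustness of the method to structured or
error-contaminated real data.

## Diversity and neutrality tests

`diversity()` reports S (segregating sites over unambiguous columns), the
mean pairwise difference k̄ (pairwise deletion: sites with N or `-` in
either sequence of a pair are excluded), and π = k̄ divided by the mean
number of usable sites per pair. `tajimas_d()` is the classical
variance-normalized contrast k̄ − S/a₁; it is undefined at S = 0 and
signals a classed condition rather than returning 0. `fus_fs()` computes
S′ = P(K ≥ k_obs | θ = k̄) under the Ewens sampling distribution and
returns ln S′ − ln(1 − S′). The unsigned Stirling numbers of the first
kind that the Ewens distribution needs overflow integers near n ≈ 130, so
the recurrence is carried entirely in log space; the distribution stays
normalized to 10⁻¹² up to at least n = 200.

`neutrality_test()` attaches one-sided (lower-tail) p-values from a
constant-size coalescent null — population growth pushes both statistics
negative, which matches the directional reading used in expansion
screening; a two-sided p-value for D is available on request. Two nulls
are provided because published practice is ambiguous about which one
Arlequin-style software conditions on: `fixed_theta` (default) simulates
with θ set to the observed k̄; `fixed_s` conditions on the observed S.
P-values use the add-one rule p = (1 + #{sim ≤ obs})/(1 + reps), so a
p-value of 0 is impossible. Simulated replicates that come out monomorphic
contribute D = 0 and Fs = +∞ (one haplotype has S′ = 1), a convention that
only makes the tests conservative. Fu's Fs is flagged significant at
p < 0.02, the conventional 5%-equivalent threshold for this statistic: its
simulation p-value null is markedly non-uniform (a naive 0.05 cut-off
rejects far too often), which is why the convention exists. The package's
own calibration run (`scripts/acceptance.R`) measures a realized size of
≈ 0.06 at the 0.02 threshold.

## Fitting the expansion and testing it

`observed_mismatch()` builds the mismatch distribution (frequency-weighted
when given a collapsed haplotype table — the two routes agree exactly),
and `fit_sudden_expansion()` minimizes the sum of squared deviations (SSD)
between observed frequencies on their support 0..d_max and the model
expectation, with the model's mass beyond d_max collected into a tail bin
compared against zero, so both vectors describe the same sample space. The
optimizer is deterministic: a coarse grid over τ ∈ [0, 2·mean] and
θ₀ ∈ [0, mean] (plus θ₁ ∈ {mean, 10·mean, 10⁴} in free mode) seeds
Nelder–Mead refinements from the best grid points, with parameters kept
non-negative through a square transform. The SSD surface genuinely is
multimodal in (τ, θ₀), hence the multi-start rather than a single descent.

**θ₁ is fixed at an "effectively infinite" ceiling (10⁵) by default rather
than estimated.** This was a genuinely open design choice and we compared
both settings. A sample taken shortly (in coalescent time) after a strong
expansion contains almost no information about the post-expansion size, so
leaving θ₁ free lets it absorb sampling variance while θ₀ collapses to its
zero boundary — and since the fitted mean must track the data mean
(≈ τ + θ₀), every unit lost from θ₀ is gained by τ, biasing τ upward. At
(τ = 3, θ₀ = 1, θ₁ = 1000, n = 50) the median point estimate over 100
simulated datasets is ≈ 3.5 with θ₁ fixed versus ≈ 3.8 free. Fixing
θ₁ = ∞ for fresh expansions is also the standard recommendation in the
mismatch literature and matches the ubiquitous θ₁ = 99999 of Arlequin
output. `theta1 = "free"` restores full estimation (capped at 10⁵ and
flagged "effectively infinite" at the ceiling), and a number fixes θ₁ at
any chosen value.

`parametric_bootstrap()` simulates `reps` datasets of size n under the
fitted parameters, re-fits each under the same θ₁ setting, and reports
upper-tail add-one p-values for the SSD (model fit) and Harpending's
raggedness index r = Σ(xᵢ − xᵢ₋₁)², plus the 2.5/97.5 percentile interval
of the bootstrap τ estimates as the 95% CI (the standard level; percentile
intervals can exclude the point estimate, which is flagged rather than
corrected). Monomorphic inputs yield a flagged degenerate fit (τ̂ = 0,
θ̂₀ = 0) that refuses to bootstrap. Calibration, measured by the package's
acceptance machinery at the generating point (τ = 3, θ₀ = 1, θ₁ = 1000,
n = 50, 200 bootstrap replicates): the 95% CI covers the true τ in ≈ 91 of
100 datasets, and the nominal-0.05 SSD test rejects at a rate consistent
with its size (0.03–0.06 across the shipped calibration runs).

## Median-joining networks

`median_joining()` follows the Bandelt construction: an ε-relaxed minimum
spanning network over the sampled haplotypes (an edge qualifies iff its
Hamming weight is within ε of the level at which its endpoints' clusters
merge under single linkage; ε = 0, the common software default, keeps all
co-minimal alternatives), then site-wise majority medians of triplets
connected in the current network are added — one per round, the candidate
with the largest cost reduction, ties broken by generation order — whenever
they reduce the total minimum-spanning cost, iterating to fixation;
finally median vectors of degree < 3 are pruned. Constant columns are
dropped up front (they cannot affect any distance), and full quasi-median
closure is deliberately out of scope: medians come only from connected
triplets, per the original heuristic. The construction is deterministic
and relabelling-invariant; exact topological identity with any particular
software's output on shared data is not promised (pruning and ε semantics
vary subtly between implementations), but every edge weight equals the
Hamming distance of its endpoints and the network always connects all
sampled haplotypes. `star_summary()` operationalizes "star-shaped": the
hub (maximum-degree sampled haplotype; ties to the more frequent, then
first input) and the fraction of the remaining haplotypes one edge away.

## Chronology

With k the sequence length, `expansion_time()` computes T = τ/(2μk) and
`rate_from_calibration()` inverts it to μ = τ/(2Tk); both quote μ in
substitutions/site/myr, the conventional reporting unit (internally
per-year). `generations_since_expansion()` adds the generation-scaled
forms u = μg and t = τ/(2uk), with t·g ≡ T. Reported values are rounded to
2 significant figures (`signif_report()`), matching how such rates and
dates are conventionally printed; raw values stay in the machine output.
`default_calibrations()` carries the four late-Quaternary anchors
(130,000; 53,000; 15,000; 11,500 years), `mole_tau_table()` the published
mole cytochrome-*b* τ estimates assigned to them, and
`calibration_table()` averages τ within each calibration class
(arithmetic mean — "average" is read literally; three low-class values are
not individually attributed to named groups in the source and carry NA
labels) before converting. Generation time is never assumed: it is a
required input wherever generation-scaled output is requested.

```{r chronology}
calibration_table(mole_tau_table())
signif_report(expansion_time(1.32, mu = 0.10))
```

## The pipeline and its decision rule

`run_pipeline()` chains the stages per haplotype group and emits one row
per group. A group is flagged as a sudden expansion when the model is not
rejected (p_SSD > 0.05 **and** p_r > 0.05) **and** at least one neutrality
test fires (Fu's Fs at 0.02 or Tajima's D at 0.05) — one defensible
codification of "supported by a mismatch distribution analysis and one or
both neutrality tests"; all thresholds are arguments. Groups below n = 4
are reported with NA statistics; a failing stage marks its group failed
and the run continues. All randomness descends from one master seed
recorded in the report attributes, and each stage can be reproduced in
isolation with its derived seed (the report is exactly re-derivable from
module calls — this is tested).

`make_fixture_panel()` is the synthetic stand-in for a deposited
multi-haplogroup alignment: by default ten groups of 14–36 sequences at
1140 bp with τ spanning 1.32–8.61 — the study conditions the package
targets — generated at θ₀ = 1, θ₁ = 1000. θ₀ = 1 represents a small
pre-expansion matriline pool while keeping groups polymorphic, and
θ₁ = 1000 puts the post-expansion population in the effectively-infinite
regime the sudden-expansion model assumes; neither value is reported by
the motivating study, so these are fixed package defaults, chosen once.

## Numerical and testing choices

* Problem sizes in the shipped checks were chosen to exercise the exact
  published protocol sizes where they exist (1000-replicate conventions
  are exercised at 200 in repeated-calibration studies, the documented
  "fast" mode): 2000 pooled replicates for the closed-form comparison, 100
  datasets × 200 bootstrap replicates for recovery/coverage, 200 runs for
  each test-size measurement.
* The Rcpp kernel evaluates the transient distribution and SSD objective;
  everything else is plain R. The kernel clamps ~10⁻²⁰ negative round-off
  in the far tail to zero.
* Tie-breaks are fixed everywhere (first occurrence for haplotype
  collapsing and hub selection, generation order for median vectors) so
  that every result in the package is reproducible bit-for-bit given a
  seed.
* Known limitations: single non-recombining locus only; the
  sudden-expansion model is fitted, not selected against alternatives
  (no spatial-expansion model, no skyline); τ estimates from single loci
  carry large genealogical variance — the bootstrap CI, not the point
  estimate, is the honest summary; and p-values inherit the granularity
  of their replicate counts.
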