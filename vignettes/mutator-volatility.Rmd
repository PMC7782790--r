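---
title: "Mutator volatility and asymmetric segregation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutator volatility and asymmetric segregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of the science it implements: the
pedigree logic behind segregant-group calling, the count models and their
fitting, the segregation simulators and their closed-form moments, the
synthetic-data generator, and the numerical and design choices that were
genuinely open.

## The pedigree and segregant groups

A single-cell lineage follows one mother cell through consecutive
divisions. For division *n* the dissected colonies are the daughter Dn,
her first and second daughters GDn.1 and GDn.2, and GGDn.1, the first
daughter of GDn.1. Replication errors are single-strand mismatches for
one cell cycle and become double-stranded mutations — visible in whole
colonies — only after the next round of replication. Tracing both
strands of every chromosome through two divisions yields four mutually
exclusive destination patterns (Da, Db, Ma, Mb; see the README table).
Two consequences drive the implementation:

* Every true mutation appears in at least two colonies, so variants seen
  in a single colony are indistinguishable from sequencing artifacts or
  within-colony sweeps and are removed (`filterToShared()`), together
  with any variant outside the intersection of all colonies' callable
  intervals.
* Once double-stranded, a mutation is carried by *all* descendants;
  all-or-none inheritance happens only at the mismatch-to-mutation
  transition. This is what makes the presence patterns exact and what
  the assignment-error detector exploits.

`assignSegregantGroups()` matches each variant's exact presence
fingerprint against the four patterns of every scorable division.
Division *n* is scorable when sublineages *n*..*n*+3 exist and are
uncensored (Mb needs the next two daughters); anything unmatched is kept
in an `unassigned` residue rather than dropped, because structured
residues are precisely the signatures of pedigree mix-ups.

### Assignment errors

Three physical mix-ups at dissection are modeled
(`injectAssignmentError()`) and two of them detected
(`detectAssignmentErrors()`):

* **Dn+1 moved in place of GDn.1** — the sublineage's Ma count drops to
  zero while a substantial fraction of its putative Db variants recur in
  later sublineages (> 25% operationalizes "substantial": a true mix-up
  produces ≈ 50%, stray noise ≈ 0%). The next sublineage consists of
  four colonies with identical content (all descend from one daughter),
  a second, independent flag.
* **GDn.1/GDn.2 swapped** — the division's Da and Db counts collapse to
  zero and the residue contains variants spanning Dn, GDn.1 and GGDn.1;
  the putative Da comparison returns what are really Ma mutations of the
  previous division.
* **GGDn.2 taken instead of GGDn.1** — a documented blind spot: the
  inheritance pattern is undistorted and no flag is raised, but the Db
  count absorbs the errors of one extra division. The generator injects
  this as extra shared GDn.1/GGDn.1 variants so tests can confirm both
  the inflation and the absence of a flag.

## Count models and model selection

Candidate models for per-division counts:

* K-component Poisson mixtures, pmf `sum_k p_k Poisson(x; lambda_k)`,
  with 2K − 1 free parameters, fitted by EM;
* the negative binomial NB(μ, θ) in the standard normalized form with
  mean μ and variance μ + μ²/θ. (A verbatim transcription of the
  printed mixture-vs-NB comparison would repeat the factor
  `(θ/(θ+μ))^x`; that form does not sum to one and contradicts the
  Poisson limit θ → ∞, so the standard `(μ/(θ+μ))^x` is used.)

Fitting and ranking choices:

* **EM** initializes component means at evenly spaced sample quantiles
  with uniform weights, runs up to 500 iterations to a relative
  log-likelihood tolerance of 1e-8, and takes the best of 10 jittered
  restarts. The observed-data log-likelihood is asserted non-decreasing
  at every iteration; a decrease aborts with an error rather than
  returning a silently broken fit. Degenerate all-equal samples converge
  to coincident components with a warning.
* **NB** exploits that the intercept-only MLE of μ is the sample mean;
  θ maximizes the profile likelihood on the log scale over
  [1e-3, 1e6]. Hitting the upper bound means the data are not
  overdispersed (the Poisson limit) and raises a warning. Tests
  cross-check against `MASS::glm.nb`, which is never the implementation.
* **Ranking** uses AIC (BIC is computed and reported; it gave consistent
  orderings in the source analysis and here). Akaike weights
  `exp(-Δ/2)` normalized over the candidate set express relative
  likelihoods. `modelSelection()` grows K only while AIC improves.
* The sample variance uses the n − 1 denominator throughout, including
  the index of dispersion D̂ = s²/x̄; at the cohort sizes used (50–200)
  the difference from the n denominator is far below the reported
  tolerances, and the choice is applied consistently to data and
  simulations.
* **How many mixture components?** The source analysis scored
  distributions "against up to four parameters", which caps mixtures at
  K = 2 (2K − 1 = 5 for K = 3), yet also displays a four-Poisson fit.
  `modelSelection()` therefore exposes `Kmax` with default 4. For the
  end-to-end recovery test the candidate set is the full-error-count
  comparison {Poisson, two-Poisson, NB}: with K = 3 mixtures (5
  parameters) admitted, they out-rank the true NB by AIC in ~20% of
  n = 50 samples *generated from the NB itself*, so a ≥95% NB-first
  requirement is only meaningful against the capped set.

The NB is equivalent to a gamma mixture of Poissons; `nbToGamma()` maps
(μ, θ) to shape θ and scale μ/θ, the continuous-volatility reading of
the overdispersion.

## Segregation simulators and their moment oracles

All rates are per haploid genome per division; chromosome copies receive
rate × f_i for genome fraction f_i. Cells inherit on average half of the
mismatches, so segregation models take mismatch rate = 2 × observed
mutation rate, while the Poisson control accumulates at the observed
rate with no segregation step.

For `T = Σ_c B_c N_c` with `N_c ~ Poisson(R f_c)` and
`B_c ~ Bernoulli(1/2)` independent across copies and divisions, the law
of total variance gives

```
E[T]  = (R/2) Σ f_c
Var T = (R/2) Σ f_c + (R²/4) Σ f_c²      (Poisson-binomial)
D     = 1 + (R/2) Σ f_c² / Σ f_c
```

and, with λ ~ Gamma(θ, mean R) drawn once per division,

```
D = 1 + (R(1+1/θ)/2) Σ f_c²/Σ f_c + R Σ f_c/(2θ)   (gamma-Poisson-binomial).
```

These closed forms (`expectedDispersion()`) were derived before the
simulators and are verified in the tests by brute-force enumeration on a
two-chromosome toy karyotype; a one-chromosome haploid karyotype is
checked against the exact zero-inflated-Poisson law. The pair models
(`simulateRepliconVariantPairs()`, `simulateDivisionVariantPairs()`)
have oracles 1 + μ/θ and 1 + 2μ/θ, and a pair correlation
(μ/θ)/(1 + μ/θ) under the shared-rate model.

Parameters that matter, with the defaults used throughout:

| parameter | meaning | default |
|---|---|---|
| μ | per-side (Dm/Mm) mean mismatches/division | 138 |
| θ | gamma shape of between-division rate variation | 60.42 |
| observed rate (yeast) | mutations/haploid genome/division | 34.5 |
| observed rate (human) | ultra-mutator equivalent | 950 |
| cohort size | divisions (cells) per D̂ estimate | 50 (pairs) / 200 (cells) |
| iterations | cohorts per ensemble | 1000–10,000 |

The human mismatch rate 1900 is exactly 2 × 950, obtained by scaling the
yeast rate by the genome-length ratio (3.03 Gb / 110 Mb). For the
gamma-rate human and yeast simulations the gamma keeps shape θ = 60.42
and is rescaled to the mismatch rate in use — one λ per division, not
per cell or per chromosome, the structure selected by the pair analysis.

## Karyotypes

Built-in tables embed full-assembly lengths: S288C's 16 nuclear
chromosomes (12.07 Mb) and GRCh38's chr1–22, X, Y (3.09 Gb), no
mitochondria or scaffolds. The source pipeline used repeat-masked
lengths, which are not published; the dispersion predictions depend on
lengths only through Σ f_i²/Σ f_i, and masking perturbs that ratio well
inside the ±5–10% tolerances carried by the affected quantities. Users
with masked lengths can supply them via `loadChromosomeTable()`. Human
diploid simulation duplicates every chromosome including X and Y (the
sex-chromosome ploidy of the original simulations is unstated; per-
chromosome ploidy is configurable for sensitivity analysis, and the
effect is absorbed by the ±10% tolerance). Chromosome order is file
order; no natural sort is imposed.

Coordinates are 1-based closed internally (GRanges); BED input/output is
converted by rtracklayer, VCF is natively 1-based. Variants at one
position with different alt alleles are distinct mutations; indels are
out of scope.

## The synthetic-lineage generator

`generateLineage()` implements the division-variant gamma-Poisson
process with all-or-none segregation: one λ_n ~ Gamma(θ, mean μ) per
division (per-haploid rate λ_n/Σ f_c, so each side's mean is μ);
conditionally independent Poisson counts per chromosome copy on the
mother and daughter sides; a Bernoulli(1/2) mask per copy deciding
Da vs Db and Ma vs Mb; colony contents assembled by the inheritance
rules; positions uniform within chromosomes and unique within a lineage
(sampled without replacement); alt alleles uniform over three bases with
a placeholder reference. The replicon-variant alternative is available
only as a pair simulator, not as a lineage generator, since the data
reject it.

What the generator deliberately does **not** emulate: sequencing depth,
read errors and allele-frequency filtering (all abstracted into the
colony-private singleton noise channel, Poisson per colony); mutation
spectra and hotspots; mutations arising inside sublineage cells (they
reach at most one sequenced colony and are again absorbed by the noise
channel); replicative aging; sister-chromatid exchange. Passing
round-trip tests therefore demonstrates the correctness of the calling
logic and the distributional machinery, not robustness to upstream
variant-calling artifacts beyond the singleton model.

### The 1:2:1 segregation tally and zero-truncation

Classifying each chromosome of a division by the fraction of a segregant
pair's mutations in the first member yields classes none/partial/all.
The Bernoulli masks alone predict 1:2:1. That prediction is exact only
when every chromosome copy carries at least one mutation: a copy with
zero mutations turns a mask-discordant (partial) configuration into
all-or-none. With per-copy rate λf_i and the gamma rate mixture, the
exact class probabilities follow from the gamma MGF
(`a_i = (1 + f_i μ_h/θ)^-θ`, `b_i` with 2f_i):

```
P(partial | counted) = (1 − 2a_i + b_i) / (2 (1 − b_i))
```

At the study-condition rate this truncation-corrected null fits both the
package's synthetic tallies and the published 876:1490:834 tally, while
a literal 1:2:1 chi-square rejects *both* — the published tally included.
The tests therefore check the literal 1:2:1 law in a high-rate regime
(μ = 600/side) where truncation is negligible and the Mendelian
mechanism is isolated, and the truncation-corrected law at the default
study conditions. Generator defaults are unchanged by any of this.

## Problem sizes and reproducibility

Cohort ensembles use 1000 iterations of 200-cell cohorts (yeast) and
single 10,000-cell cohorts (human); pair-model ensembles use 10,000
cohorts of 50; the end-to-end recovery study uses 100 seeded replicates
of 53-division lineages — sizes at which every reported quantity's
Monte-Carlo error is several-fold smaller than its comparison tolerance.
Every stochastic entry point takes a `seed`; equal seeds give
bit-identical results, and the command-line wrapper records seed,
configuration and package version in a run manifest next to each output.

## Known limitations

* Mb at the lineage tail is evaluated over at least two downstream
  sublineages; the last three divisions of any lineage are structurally
  unscorable, and Mb(N−2) is indistinguishable from Ma(N−1) — such
  variants stay unassigned rather than being guessed.
* The GGD-swap error is undetectable by design of the pedigree (the
  documented blind spot); only its Db inflation is modeled.
* The false-negative rate of the upstream variant-calling pipeline is
  not modeled; callable intervals are taken as given.
* No selection, death or clonal competition in the burden trajectories;
  cumulative burden is a sum of independent per-division draws.
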