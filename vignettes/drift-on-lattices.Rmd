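---
title: "Neutral drift under spatially constrained mating: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neutral drift under spatially constrained mating: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftlattice)
```

## The model

`driftlattice` simulates a single neutral locus with alleles A and a in a
diploid population of constant size N = L_r × L_c. One individual occupies
each site of a periodic lattice (a torus: coordinates wrap modulo the
lattice dimensions). A replicate proceeds in four steps:

1. **Initiation.** Each of the 2N gene copies is independently allele A with
   probability `p0`; an individual's unordered genotype is the pair of its
   copies (AA, Aa or aa, stored as 0, 1 or 2 copies of A).
2. **Mate selection.** Every individual, acting once as a focal parent,
   draws a mate uniformly from its candidate set: the 4, 6 or 8 nearest
   lattice sites (`g4`, `g6`, `g8`) or all N − 1 other individuals (`gnf`).
   Selfing is never allowed; mate choice is blind to genotype.
3. **Gamete generation.** Each parent transmits one of its two alleles with
   probability 1/2 (a heterozygote's two orderings are the same state, so a
   heterozygote transmits A or a with equal chance; homozygotes transmit
   deterministically).
4. **Birth.** The two gametes form the offspring, which occupies the focal
   parent's site in the next generation.

Generations are discrete and synchronous: all offspring are computed from
the parental generation, then the whole population is replaced at once. The
replicate ends at the first generation T_h at which the allele frequency
f(A) = (2 n_AA + n_Aa)/2N reaches 0 or 1; with no mutation or migration that
state is absorbing. Runs that have not fixed by `max_generations` are
flagged `capped` and excluded (with a count) from mean fixation times and
distribution fits, never silently truncated.

Three modelling choices deserve emphasis, because the verbal description of
"random mating in a neighbourhood" leaves them open:

- **Individuals are monoecious.** Reproduction is biparental but no sexes
  are assigned; any neighbour is an admissible mate.
- **One offspring per focal parent.** Every individual is a focal parent of
  exactly one offspring (keeping N constant) and may additionally be drawn
  as a mate by any number of neighbours. If two individuals each happen to
  pick the other, those are two independent offspring events.
- **Synchronous replacement.** No offspring mates within the generation it
  is born.

## The mating topologies

`g4` and `g8` are the von Neumann and Moore neighbourhoods. `g6` realises a
hexagonal lattice on square storage by treating even-numbered rows as
shifted left by half a cell: an odd-row site (r, c) has neighbours
(r, c±1), (r−1, c), (r−1, c+1), (r+1, c), (r+1, c+1), and an even-row site
the mirrored set. This offset convention yields a 6-regular symmetric graph
provided the number of rows is even — with an odd row count the parity of
the top and bottom rows would collide across the periodic seam, so that
configuration is rejected rather than silently mis-wired. On degenerate
lattices (e.g. 2×2 under `g4`) distinct geometric directions can wrap onto
the same site; duplicates are kept in the candidate list so every direction
retains equal selection probability. Tests exercise such lattices; real
experiments use L ≥ 10.

## Statistics

- **Allele frequency** f = (2 n_AA + n_Aa)/2N and **observed
  heterozygosity** H = n_Aa/N are plain counts.
- **Inbreeding coefficient** F = 1 − H/(2pq) with p = f, q = 1 − f;
  undefined in a fixed population. No small-sample correction is applied to
  the expected heterozygosity 2pq.
- **Inverse-Gaussian fit.** T_h is a first-passage time of a
  near-Brownian frequency walk, so its distribution across replicates is
  modelled as inverse Gaussian IG(μ, λ) and fitted by the closed-form
  maximum-likelihood estimates μ̂ = x̄, λ̂ = n/Σ(1/xᵢ − 1/μ̂). The MLE is
  preferred over moment matching because it is exact, deterministic and
  hand-checkable (for {1, 2, 3}: μ̂ = 2, λ̂ = 9). Samples with zero
  dispersion are rejected as degenerate rather than fitted with λ = ∞.
- **Heterozygosity decay.** For an ideal random-mating population,
  H(T) = H₀(1 − 1/2N_e)^T. `fit_het_decay()` fits log H linearly on T by
  OLS inside a user-chosen window, dropping non-positive H values with a
  count, and back-transforms the slope b to N_e = 1/(2(1 − e^b)). A
  non-negative slope is reported as a no-decay error instead of an infinite
  N_e. The mean absolute relative residual is returned so that exponential
  and non-exponential decays can be told apart: panmictic curves fit with
  residuals well under 5%, while locally mating populations decay
  non-exponentially (fast early coarsening, then slow boundary-limited
  loss) and fit visibly worse.
- **Size scaling.** T_ave is proportional to N to a good approximation, and
  the headline statistic is the through-origin least-squares slope
  Σ(N·T_ave)/Σ(N²) in generations per individual, chosen because the claim
  being quantified is proportionality; the with-intercept OLS slope is
  reported alongside as a sensitivity diagnostic. Equivalent-size ratios
  are slope(gnf)/slope(gk).

## Effective size of this mating scheme

The scheme's drift is weaker than Wright–Fisher sampling. Each parent
contributes exactly one gamete as a focal parent plus, in panmixia, a
Binomial(N − 1, 1/(N − 1)) ≈ Poisson(1) number as a chosen mate, so the
variance of its gamete count is ≈ 1 rather than the Wright–Fisher ≈ 2.
Decomposing the one-generation variance of f at Hardy–Weinberg proportions
gives Var(Δf) = (3/4)·f(1−f)/2N, i.e. an effective size N_e = 4N/3 and an
expected mean fixation time from p = 1/2 of 4·ln 2·N_e ≈ 3.70 N generations
for `gnf`. Simulations reproduce this closed form within Monte-Carlo error,
which is a useful end-to-end calibration of the engine (alongside the exact
81-state Markov-chain oracle for the 2×2 panmictic population used in the
tests). Spatial topologies slow fixation further, and increasingly so on
larger lattices: under local mating, gametes diffuse only one lattice step
per generation, so the fixation time of an L×L population grows faster than
N, and the fitted through-origin "slope" rises with the size range used.
Desk-scale sweeps therefore understate the large-lattice slopes and the
spread between topologies; the ordering and the qualitative conclusions are
insensitive to scale.

## Problem sizes and seeding

Default experiments run lattice sides {10, 20, 30} (N = 100, 400, 900) with
200 replicates per cell at p0 = 0.5. At 200 replicates the standard error
of T_ave is ~5% of its value, which is adequate for slope fitting, and a
full four-topology sweep completes in minutes on one CPU. The
heterozygosity experiment defaults to N = 400, 200 replicates and a
200-generation horizon, where the topology ordering of mean H separates by
many standard errors. The generation cap defaults to 1000·N — two orders of
magnitude above typical fixation times — so capping indicates a
pathological configuration rather than a tail event.

Each replicate i of a cell (topology, N) is seeded by folding
(base seed, topology index, N, i) modulo 2³¹ − 1 with a fixed multiplier,
and every stochastic step (initiation, mate draws, gamete draws) consumes
that replicate's R RNG stream in fixed row-major site order inside the
compiled generation step. Replicates are therefore reproducible
individually, independent of execution order or batching; the same
(parameters, seed) pair gives a bit-identical trajectory.

## What the simulator does and does not emulate

The simulated populations satisfy the textbook idealisations — no
selection, mutation, migration or overlapping generations; constant N;
random (genotype-blind) mating within the chosen neighbourhood. Passing
tests therefore validate the drift mechanics and the statistics, not
realism about natural populations: real habitats have edges rather than
periodic wrap, uneven density, sex structure, variable fecundity and
long-distance dispersal, all of which change N_e and the cluster geometry.
The cluster statistics in particular describe this model's coarsening
pattern (homozygous patches with heterozygote boundaries), which is a
qualitative, not calibrated, picture of spatial genetic structure.

## Known limitations

- Single biallelic locus; no multi-locus statistics or linkage.
- The hexagonal topology requires an even row count (documented above).
- Fixation-time "slopes" are range-dependent for local topologies (see the
  effective-size section); comparisons between topologies should be made at
  matched size ranges.
- The inverse-Gaussian law is an approximation to the true first-passage
  distribution of a finite-population walk; tests require it to beat a
  moment-matched normal, not to pass a distributional goodness-of-fit test.
- `boundary_heterozygote_fraction()` reports two boundary definitions
  (between opposite clusters; adjacent to any homozygote) because "on the
  boundary" is otherwise ambiguous; both are returned rather than blended.
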