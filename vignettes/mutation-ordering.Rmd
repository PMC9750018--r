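---
title: "Placing and ordering somatic mutations on a single-cell phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Placing and ordering somatic mutations on a single-cell phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutorder)
```

## The model and its assumptions

`mutorder` answers a narrow question well: *given* a rooted bifurcating
phylogeny of `J` single tumor cells with branch lengths, and noisy per-cell
genotype calls at `I` sites, on which branch did each mutation arise, and in
what temporal order? It does **not** estimate the tree, the transition rates
or the error rates; all of those are inputs (or priors to integrate over).

Three assumptions do the heavy lifting:

* **One origin per site (infinite sites).** A mutation is acquired on
  exactly one branch and is inherited by every cell in the clade below it;
  it is never lost. This is what turns a posterior over genotype histories
  into a posterior over `2J − 2` branches. Sites evolving under appreciable
  back-mutation violate this; the finite-sites simulator exists precisely
  to measure how badly.
* **Branch-wise independent Markov evolution.** Binary genotypes follow a
  one-rate irreversible chain; ternary genotypes follow the three-state
  chain with rates λ1 (0→1), λ2 (1→2) and direct 0→2 at λ1λ2. Only the
  products λ·t matter: no molecular clock is assumed and branch lengths are
  taken in whatever units the input tree uses.
* **Cell-wise independent observation errors.** Conditional on the true
  genotype, each cell's call is corrupted independently with false-positive
  rate α and false-negative (dropout) rate β. In the ternary error matrix a
  heterozygote drops either allele with probability β/2 each, and a true
  homozygous non-reference genotype is always observed as 2.

## Parameters that matter

| Parameter | Meaning | Default / typical | Notes |
|---|---|---|---|
| λ (binary), λ1 | acquisition rate per site per unit length | 1e-7 | only λ·t matters; the posterior is insensitive to λ once normalized, so literature point values are fine |
| λ2 | 1→2 rate (ternary) | 1e-2 | λ2 = 0 reduces the mutation process exactly to the binary model |
| α, β | FP / FN probabilities | data-set specific (published SCS estimates range from ~0.015 to ~0.3 for α, ~0.02 to ~0.5 for β) | scalars or per-site-per-cell matrices |
| θ | credible-set complement | 0.05 | greedy prefix by decreasing posterior |
| M | Monte Carlo draws over priors | 200 | Rao-Blackwellized: numerators, not per-draw posteriors, are averaged |

Priors for integration are Beta(a, b) on α and β and Gamma(shape, scale) on
the rates, mirroring how error rates are reported (means a/(a+b)) and how
rate uncertainty is usually encoded.

## Numerical choices

* All branch products are computed in log space; normalization uses
  log-sum-exp, so 1000-cell trees with λ = 1e-7 pose no underflow problem.
* The ternary transition matrix has a removable singularity at
  λ2 = λ1(1 + λ2); within 1e-12 of it the entry `P01` switches to its limit
  `λ1 t e^(−λ1(1+λ2)t)`. The matrix is implemented from the closed form of
  `exp(Qt)` and is verified in the test suite against a numerical matrix
  exponential to 1e-10, including the singular line.
* Zero-length branches are legal: `P01(0) = 0` removes them from the prior
  naturally. If *every* branch has zero acquisition probability the prior is
  reported as undefined rather than silently uniform.
* MAP ties (exact ties occur for symmetric trees and data) are broken
  toward the smallest branch id and flagged. Credible-set construction uses
  a stable sort, so ties there are also deterministic.
* Sites whose likelihood is zero on every branch (possible with α = β = 0
  and contradictory data, e.g. observed carriers spanning both root clades)
  are reported as per-site failures, not fatal errors.
* Joint-order credible sets enumerate assignments lazily in decreasing
  product probability; the space has `(2J−2)^I` elements, so enumeration is
  capped (default 1e6) and truncation is flagged.

## Missing and ambiguous data

Cells missing (`-`) at a site are excluded by pruning the tree to the
observed cells and suppressing degree-2 nodes; merged path lengths are
summed. The posterior is computed on the projected tree (its `2J_i − 2`
branches) and mapped back: mass on a merged branch is split over its
original-branch path **proportionally to original branch lengths** (uniform
if all are zero). This back-mapping rule is our design choice — under small
λ the prior probability of a branch is proportional to its length, making
length-proportional allocation the model-consistent split — and is the one
place the output depends on a convention rather than the model. Branches
pruned away entirely (including any stem above the projected root) get
posterior zero.

Ambiguous calls (`?`) keep the cell but replace the point observation with
a weighted sum over observable states, uniform by default and overridable
per cell. Weights span all states of the declared mode; we did not restrict
them to "reachable" states since nothing in the model requires it.

## What the simulators emulate — and what they do not

* `simulate_tree("coalescent")` draws standard neutral coalescent
  genealogies (exponential waiting times, rate `choose(n,2)`), with a
  single scale knob in place of explicit demography. It does *not* model
  population growth, effective population size, or read-level sequencing,
  the way dedicated single-cell coalescent simulators do.
* `simulate_tree("random_split")` is the recursive random-splitting
  algorithm (via `ape::rtree`) with i.i.d. exponential branch lengths of
  mean 0.2 — the regime the model-based validation scenarios use.
* `simulate_placements` samples sites from the exact placement prior, so
  perfect-data round trips are a sharp correctness check: with α = β = 0,
  no missing data and no loss, MAP placement must recover every site
  (this is asserted, not assumed, in the tests).
* `introduce_losses` implements the k-round reading of the loss protocol:
  per mutation, up to `k` rounds each propose one uniform branch and accept
  with probability `r`; an accepted loss reverts the whole descendant clade
  to 0. The protocol's written description is ambiguous between this and a
  single-proposal reading; we fixed one reading and documented it.
* `simulate_finite_sites` runs a two-state Gillespie simulation along each
  branch and keeps the full event list, defining the "true location" of a
  site as the branch of its first 0→1 event.

A green test on these simulators establishes internal consistency of model,
simulator and inference. It does **not** establish robustness to real SCS
pathologies outside the model: doublets, read-depth-dependent errors,
copy-number artifacts, or mis-specified trees.

## Metric conventions

Order accuracy counts all true ancestor–descendant pairs plus true
same-branch pairs; a sequential pair inferred onto one common branch counts
as *incorrect*, while a same-branch pair is correct only if inferred onto
one common branch. Adjacent-order accuracy restricts to pairs on
parent/child branches (and same-branch pairs — a documented switch excludes
them, since the convention is implied rather than stated in our source
material for the denominator). Replicates are pooled by summing counts,
never by averaging ratios.

## Known limitations

* The ternary→binary reduction (λ2 = 0) is exact for the mutation process
  and priors at any error rates, but binary and ternary *posteriors* agree
  only when β = 0, because the ternary error model halves dropout per
  allele. This is a property of the error model, not a bug; the test suite
  checks the reduction exactly where it is mathematically valid.
* No estimation of α, β or λ from data; heavily mis-specified error rates
  degrade placement accuracy (the simulation grid quantifies the decay).
* Parallel and back-mutations are outside the inference model; under
  finite-sites simulation with high reversal rates the "true branch" itself
  becomes ill-defined and accuracy necessarily drops.
* Polytomies must be resolved (deterministically, zero-length) before
  inference; the model is defined on bifurcating trees.
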