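---
title: "Substitution-model complexity and relative divergence times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Substitution-model complexity and relative divergence times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question

Molecular dating pipelines habitually reach for parameter-rich substitution
models (GTR+Γ and beyond) on the grounds that branch-length error propagates
into node-age error. But divergence-time estimation only consumes *relative*
branch lengths: node ages are ratios of linear combinations of branch lengths.
If a simple model (Jukes–Cantor) underestimates every branch by roughly the
same factor, the ratios — and hence the times — survive. `relchron` provides a
self-contained simulation-and-analysis laboratory for quantifying exactly when
that argument holds and when it breaks: it simulates clocklike sequence
evolution on a timetree, estimates distances and maximum-likelihood branch
lengths under a ladder of models, dates trees with a calibration-free
relative-rate method, and measures agreement between the simple-model and
complex-model estimates.

## The simulation model

Sequences evolve along a known timetree under a continuous-time Markov chain.
The default generating model is GTR+Γ with:

* base composition π(T, C, A, G) = (0.25, 0.33, 0.31, 0.11) — a biased,
  realistic composition;
* exchangeabilities with a four-fold transition bias
  (`ag = ct = 4`, all others 1). The transition/transversion bias is the one
  structural asymmetry that JC ignores most; 4 is a typical empirical value;
* gamma rate heterogeneity with shape α = 0.25 — strong site-to-site rate
  variation, the regime where simple models underestimate divergence most;
* 5,000 sites.

The timetree is a *completely unbalanced* (caterpillar) tree with 16 tips and
root age 3 time units; internal-node ages are uniformly spaced
(`root_age * k / (n_tips - 1)`), the most regular, fully reproducible choice
for a shape that the source material depicts but does not tabulate. The
caterpillar maximizes the spread of branch lengths (the root-attached tip
spans the whole tree height), which is deliberately hostile: it emulates
sparse taxon sampling with long branches.

The strict clock runs at 0.1 substitutions/site/time-unit (the baseline, 1×)
and is accelerated 2–10× in `run_simstudy()`. At 10× the pooled median
TN+Γ pairwise distance is ≈ 4.4–4.7 substitutions/site — far beyond any
realistic data set, probing the saturation regime.

Two deliberate asymmetries between generation and inference mirror standard
practice: simulation draws a *continuous* gamma rate per site (shared across
the whole tree), while likelihood inference uses the discrete 4-category
approximation; and simulation uses the exact generating exchangeabilities
while inference re-estimates them. Parameter-recovery results therefore
include the (small) discretisation bias a real pipeline would have.

What the generator does *not* emulate: indels and alignment error (gaps can
be represented but are never generated), among-lineage rate variation
(available via `per_branch_rate_factors`, off by default), non-stationary
composition, and recombination. Passing tests on this generator say nothing
about those failure modes.

## Distances

`nt_distance()` implements the closed-form corrections (p, JC, K2, TN93),
each with a +Γ variant in which every `-log(x)` becomes
`α (x^{-1/α} - 1)`. Saturated pairs (a log/power argument ≤ 0) are `NA` —
never negative or infinite — and are excluded-but-counted by every summary.
Gap/`N` sites are removed per pair (pairwise deletion); TN93 uses the base
frequencies of the pair being compared. The +Γ shape is supplied by the
caller (the generating α in the simulation study) or can be estimated once on
the whole alignment by ML; per-pair α estimation is deliberately not offered
(it is unstable).

## Likelihood and branch lengths

`log_likelihood()` is a Felsenstein-pruning implementation over compressed
site patterns with per-node rescaling, discrete-Γ averaging (equal category
weights, category rates = bin means), ambiguity handled as partial
likelihoods. It is validated against exhaustive enumeration over all
internal-state assignments on every 3- and 4-tip topology, for every family
including the non-reversible UNREST model.

`fit_branch_lengths()` delegates the reversible-family optimization to
`phangorn::optim.pml` (branch lengths always; exchangeabilities and the gamma
shape when free; base frequencies are empirical counts), then maps the result
back onto the rooted topology. One subtlety deserves emphasis: under a
reversible model the likelihood identifies only the *sum* of the two
root-adjacent branch lengths. The package's convention is to split that sum
so the two root children's mean lineage depths balance
(`b1 + H(c1) = b2 + H(c2)`, clipped to the nonnegative range) — the same
depth recursion the dating method uses, and exact on clocklike data. All
model families share this convention, so root-edge comparisons between models
are conventional but consistent.

`fit_unrest()` (the optional non-reversible tier) optimizes twelve rates and
all branch lengths jointly (L-BFGS-B on log scale, branch lengths bounded to
[1e-8, 20], rates to [1e-4, 1e4]), warm-started from the nested GTR fit so
the UNREST optimum can never fall below it. The root split is genuinely (if
weakly) identified here; after a final line search over the split, the
presentation convention above is applied only when it costs a negligible
amount of likelihood (0.5 units), otherwise the ML split is kept.

## Relative times

`relative_times()` implements a relative-rate recursion: bottom-up, tips have
mean lineage depth `H = 0` and an internal node with children *j*, *k* over
branches *b_j*, *b_k* gets `H = ((b_j + H_j) + (b_k + H_k)) / 2`; top-down,
`age(root) = H(root)` and each child's age is the parent's age times
`H_child / (b_child + H_child)`. This is a RelTime-style estimator in its
arithmetic-mean form — chosen over the geometric-mean variant because it is
simpler, exact on clocklike input (proved in tests to 1e-10), and linear in
the branch lengths; it is not a clone of any released implementation and has
no outlier-handling heuristics. A zero-length lineage collapses the child to
age 0 with a warning. Outgroups must be pruned before dating
(`prune_outgroup()`); the function refuses trees still containing taxa the
caller flags as outgroup.

Chronograms are normalized so internal-node ages sum to 1, making estimates
from different models directly comparable without calibrations. Uncertainty
comes from a site-resampling bootstrap (percentile intervals; the observed
estimate is included in the replicate pool so intervals always contain the
point estimate) — a substitute for analytical confidence intervals, not a
reimplementation of them.

## Comparison statistics

* Through-origin regression: slope `Σxy/Σx²`; R² is the squared *uncentered*
  correlation `(Σxy)²/(Σx² Σy²)`, bounded in [0, 1] and symmetric — the
  natural definition when the fit is constrained through the origin.
* MRAE: `100/n Σ |t_s − t_c| / t_c` over nodes with `t_c > 0`, the
  complex-model estimate as denominator.
* Stratified slopes: branch categories (short = below the mean; long = more
  than one sample SD above the mean; ties are intermediate — strict
  inequalities, sample SD with n−1) and node depth regions (shallow ≤ 30% of
  root age, deep ≥ 70%, with a 50% option for trees whose internal nodes are
  all young). Strata are always computed on the *complex-model* estimates.
* Interval overlap: closed intervals, boundary touching counts as overlap.
* Regression points are the internal nodes including the root (both models
  assign it an age); strata with fewer than two points report `NA` rather
  than raising.

## Problem sizes and numerical choices

The packaged experiments are sized for a single desktop CPU: the simulation
study runs 16 tips × 5,000 sites over 6 multipliers × 10 replicates; oracle
likelihood checks use 6-site alignments on all 3-/4-tip topologies; the
subsampling experiment uses a 100-tip caterpillar with 1,000 sites, nested
subsets of 10–90 ingroup taxa and 20 replicates, with the reference model's
exchangeabilities and gamma shape estimated once on the full alignment and
held fixed across subsets (only branch lengths are refitted per subset).
Branch-length bounds are [1e-8, 20] substitutions/site; optimization
tolerance |ΔlnL| < 1e-8 per phangorn's criterion, 50 cycles maximum;
replicate seeds derive from one master seed by a fixed multiplicative
counter scheme (`derive_seed()`), so every artifact is reproducible from a
single integer.

## Known limitations

* The continuous-gamma generator combined with discrete 4-category inference
  at α = 0.25 leaves a visible recovery bias: fitted GTR+Γ branch lengths
  regress on the truth with slope ≈ 0.92 (R² > 0.99). Refitting with eight
  categories moves the slope to ≈ 0.94, confirming the discretisation as the
  source. Four categories remain the default because that is what practical
  ML dating pipelines use; treat absolute branch lengths at very small α
  accordingly.
* At the default study conditions the JC-vs-GTR+Γ relative chronograms agree
  to a through-origin slope within 1.05 and R² > 0.98, but the per-node MRAE
  is typically 12–17%: with only 16 taxa and α = 0.25 the underestimation of
  long branches is strongly nonuniform, and the relative-rate method cannot
  redistribute it. This is the sparse-sampling distortion the simulation is
  designed to expose, and it is the expected behaviour of the method, not an
  optimization failure — the same comparison on the GTR+Γ side recovers the
  true relative ages to a few percent per node.
* The dating recursion has no rate-outlier handling; pathological branch
  length estimates propagate into ages.
* Bootstrap intervals are percentile intervals under site resampling only;
  they do not capture topology or model uncertainty.
* Amino-acid models, partitioned analyses, calibration densities and Bayesian
  dating are out of scope.
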