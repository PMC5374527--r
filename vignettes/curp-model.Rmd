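---
title: "The CURP sharing model: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The CURP sharing model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`curp` implements CURP (Cooperation Under Resource Pressure), an
agent-based model of food sharing in small, well-mixed forager
populations, together with the statistical apparatus used to study it:
Latin Hypercube parameter screening with random-forest variable
importance, and kernel-density maps of the evolved strategy space under a
resource-pressure sweep. This vignette documents the model, the package's
numerical and design choices, and what the reduced-scale experiments can
and cannot show.

## The model

A constant population of `n_people` agents plays a sharing game in
discrete periods. Each period:

1. **Resource draw.** Every agent independently acquires one unit of
   energy with probability `prob_resource` (there is no storage; energy
   does not carry across periods).
2. **Sharing.** The lucky agents act once each, in a fresh random order.
   A donor samples a tournament of currently needy recipients — agents
   who drew nothing this period and whose accumulated energy is still at
   or below the survival threshold `min_energy` — of size
   `ceiling(sharing_tournament_size * pool)`, at least one. With
   probability `|correlation|` she picks the tournament's extreme member:
   the most generous (highest `given_energy`) if her `correlation` is
   positive, the least generous if negative; otherwise a uniform-random
   member. She then transfers `given_energy` of her unit. A recipient
   pushed strictly above `min_energy` stops receiving immediately
   (asynchronous pool update).
3. **Survival.** An agent survives the period — gaining one fitness
   unit — only if her energy strictly exceeds `min_energy`. Donating can
   therefore be individually costly: a donor keeping `1 - given_energy`
   at or below the threshold starves that period.

After `rounds_per_generation` periods, strategies evolve. In a fresh
random order each agent samples `ceiling(strategy_tournament_size *
n_people)` other agents and copies the strategy (both heritable traits,
`given_energy` and `correlation`) of the fittest sampled agent if — and
only if — that fitness strictly exceeds her own. Each agent then mutates
with probability `prob_mutation`, drawing a fresh strategy uniformly from
the space `[0, 1] x [-1, 1]`. Fitness is reset at the boundary, so
imitation always compares success within the same generation.

A positive `correlation` implements indirect reciprocity — giving
preferentially to agents with a generous disposition — without any memory
of past interactions; the partner-choice cue is the candidate's heritable
`given_energy` itself.

## Parameters and their defaults

| parameter | meaning | default | sweep range |
|---|---|---|---|
| `n_people` | population size (constant) | 300 | 100–500 |
| `prob_resource` | per-period acquisition probability | 0.5 | 0–1 |
| `min_energy` | survival threshold (fraction of a unit) | 0.5 | 0–1 |
| `sharing_tournament_size` | donee tournament, fraction of the needy pool | 0.01 | 0–1 |
| `strategy_tournament_size` | imitation tournament, fraction of the population | 0.01 | 0.01–1 |
| `prob_mutation` | per-generation strategy reset probability | 0.01 | 0.01–1 |
| `rounds_per_generation` | periods between strategy updates | 10 | 10–50 |

The defaults are the reference parameterisation of the resource-pressure
grid sweep (`grid_design()`), which crosses `prob_resource` and
`min_energy` over `seq(0.2, 0.8, 0.1)` with 30 replicates per cell. The
sweep ranges are those used by the Latin Hypercube screen
(`lhs_ranges("paper")`).

## Design choices in ambiguous corners

Several micro-mechanisms admit more than one reading; the package fixes
them as follows.

**Initial strategies** are uniform on the full strategy space, the same
distribution mutation draws from: unbiased, and it makes the mutation
limit (`prob_mutation = 1`) exactly stationary from the first generation.

**Donation base.** A donor transfers `given_energy` of the *unit*, i.e.
keeps `1 - given_energy`. Because only resource-drawers donate and they
always hold exactly one unit when acting, "fraction of the unit" and
"fraction of current energy" coincide; no configuration switch is
offered for a distinction without behavioural content.

**Donee eligibility.** An agent can receive while she drew nothing this
period *and* her energy is at or below `min_energy`; at exactly the
threshold she still starves (survival is strict), so she remains
eligible. We also explored the alternative rule in which eligibility
depends on current energy alone, so that an over-generous donor can
herself be rescued later in the same period. That variant makes
selection fully inert in abundance (any strategy survives, and the
population mean stays pinned at its initial value instead of being
truncated below `1 - min_energy`), but it changes none of the package's
headline statistics, and the stricter rule keeps the recipient pool
semantics — donations flow from the lucky to the unlucky — so the
stricter rule is the one implemented.

**Tournament counts** are `ceiling(fraction * pool)`, clamped to
`[1, pool]`; the imitation tournament additionally excludes the focal
agent (cap `n_people - 1`). The ceiling-with-minimum rule guarantees
non-empty tournaments at the reference setting of 1%.

**Tie-breaks.** Equal `given_energy` in a donee tournament and equal
fitness in an imitation tournament are broken uniformly at random, so no
agent index is ever privileged.

**Asynchronous updates.** The recipient pool is recomputed before every
donor acts, and imitation reads current (possibly already-updated)
strategies, matching a sequential agent scheduler. Mutation is applied
after the imitation pass, independently per agent.

**Recording.** Population means of the two strategy variables are
recorded every period; since strategies only change at generation
boundaries, `record = "generation"` stores the identical information one
row per generation and is the compact default for batch runs.

## Randomness and reproducibility

All randomness — including the compiled core — flows through R's RNG, so
a run is a pure function of `(params, seed)`. Batch designs derive one
seed per run from a master seed by a linear map modulo the Mersenne prime
2^31 − 1 (`derive_seed()`); seeds are distinct within a design and each
run can be re-executed in isolation, which makes results independent of
worker count and execution order and lets interrupted batches resume from
checkpointed traces.

## The screening analysis

The sensitivity screen asks which of the seven parameters drive the
model's long-run behaviour. `lhs_design()` stratifies every parameter
range into one stratum per design point (exactly one jittered sample per
stratum, via `lhs::randomLHS`); integer parameters are rounded after
sampling, which preserves stratification up to rounding. Each run records
its mean-strategy trajectory; `build_feature_table()` reduces a run to
its post-burn-in time averages (default) or to per-period rows, together
with the time-period variable. The sensitivity pipeline uses per-period
rows thinned to every fifth record: with per-experiment aggregates the
time-period value collapses to the run length, a deterministic function
of `rounds_per_generation`, and the response would trivially encode that
predictor whenever it varies across the design; per-period rows keep the
time axis a genuine within-run variable, and thinning costs little
because the trajectories are strongly autocorrelated. The three recorded state variables are
z-scored — they live on incomparable scales — and compressed by PCA;
the first component, with its sign anchored so the `given_energy` loading
is nonnegative, is the regression response. A random forest (default 800
trees, 5 candidate features per split, the optimum of the published
10-fold cross-validated grid search reproduced by `cv_grid_search()`)
yields per-parameter relative importance, normalized to sum to one.

Two importance measures are exposed: `impurity` (default; total
split-quality improvement, the measure behind the printed sum-to-one
ranking) and `permutation_oob` (increase in out-of-bag MSE after
permuting a predictor; negative raw values from uninformative predictors
are floored at zero before normalization).

In this implementation the screen robustly ranks `prob_mutation` and
`min_energy` as the dominant drivers at desk scale: the mutation rate,
sampled over `[0.01, 1]`, pins the population at the centre of the
strategy space for most of its range, and the survival threshold sets
both the cooperative norm (`given_energy` near `1 - min_energy`) and the
drift truncation. `prob_resource` moves the system between regimes only
where mutation is weak, a small slice of the sampled volume. The
acceptance suite states the published ranking as its expectation and
reports the discrepancy rather than adjusting the apparatus toward it.

## The resource-pressure sweep

For each grid cell the post-burn-in `(mean given_energy, mean
correlation)` records of all replicates are pooled and smoothed with an
axis-aligned Gaussian kernel (Scott's rule bandwidth `sd * n^(-1/6)` per
axis, recorded in the output) on a lattice over `[0, 1] x [-1, 1]`,
renormalized to integrate to one; degenerate clouds return a labelled
point mass. `regime_summary()` quantifies the three qualitative regimes:

- **low stress** — selection barely acts; replicates scatter by drift
  while each stays nearly constant;
- **high stress** — survival is rarely attainable and the population
  churns; flagged when the temporal variance of mean `given_energy`
  exceeds `var_high` (default 0.02; a trace bouncing uniformly over
  `[0, 1]` has variance 1/12);
- **intermediate** — the population coordinates on sharing the surplus:
  mean `given_energy` within `coord_tol` (default 0.15) of
  `1 - min_energy` with positive mean `correlation`.

The classification checks instability first, then coordination; both
thresholds are exposed.

At the centre cell (`prob_resource = 0.5`, `min_energy = 0.5`) the
coordinated state is *metastable* in this implementation: a donor giving
exactly the surplus `1 - min_energy` keeps precisely threshold energy and
starves under the strict survival inequality, so the norm sits just below
the surplus, recipients need two donations instead of one, and the
population episodically falls off the cooperative state before
re-coordinating. Time-averaged statistics at this knife-edge cell
therefore mix coordinated and collapsed episodes — visible in the
regime summaries the package computes.

## Problem sizes

The package's experiment presets are sized for a single core: screens of
200 Latin Hypercube points at 150 generations (population capped at 200),
and grid cells at the reference population of 300 with 2000 generations
and 10 replicates, with burn-in fixed at the first 20% of each run — the
same proportion the full-scale study discards. Reduced grid runs keep
the full population because the donee tournament is a 1% fraction of the
needy pool: below roughly 150 agents it collapses to a single candidate,
partner choice becomes selectively neutral, and the indirect-reciprocity
signal the sweep is meant to exhibit is destroyed by the reduction
itself.

## What the synthetic experiments do and do not show

All inputs are generated by the simulator; there is no external data.
Passing tests demonstrate internal correctness (conservation laws,
selection-law frequencies, stratification, estimator oracles) and
reduced-scale reproduction of the model's qualitative dynamics. They do
not validate the model against empirical foraging records, and
reduced-scale importance values need not match full-scale ones where the
dynamics are still transient at 150 generations. The model itself
abstracts away storage, space, networks, demography and death; its
regimes speak to the evolutionary logic of sharing norms, not to any
specific society.
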