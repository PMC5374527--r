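# curp

An R implementation of **CURP** (Cooperation Under Resource Pressure): an
agent-based model of food sharing in small, well-mixed forager
populations, plus the statistical machinery used to study it — Latin
Hypercube sensitivity screening with random-forest variable importance,
and kernel-density maps of the evolved strategy space under a
resource-pressure sweep. It is aimed at researchers in evolutionary game
theory, behavioural ecology and computational archaeology who want a
fast, seedable, fully scriptable version of the model.

## The model

`n_people` agents live through discrete periods. Each period an agent
acquires one unit of energy with probability `prob_resource`. Lucky
agents each donate a heritable fraction `given_energy` ∈ [0, 1] of their
unit to a needy recipient — an agent who drew nothing and still holds at
most the survival threshold `min_energy` — chosen from a small
tournament: with probability |`correlation`| the most (if
`correlation` > 0) or least (if < 0) generous candidate, otherwise at
random. An agent survives a period only if her energy strictly exceeds
`min_energy`; fitness counts surviving periods. Every
`rounds_per_generation` periods each agent imitates the strategy
(`given_energy`, `correlation`) of the fittest of a sampled tournament if
that fitness strictly beats her own, then mutates to a uniform-random
strategy with probability `prob_mutation`.

A positive `correlation` is indirect reciprocity: giving preferentially
to generous dispositions without tracking past interactions. The
interesting question is how the evolved (`given_energy`, `correlation`)
distribution responds to resource pressure — the combination of
stochastic scarcity (`prob_resource`) and physiological need
(`min_energy`).

The simulation core is compiled (Rcpp) and runs roughly a million
agent-periods per second; all randomness flows through R's RNG, so every
run is reproducible from `(params, seed)`.

## A worked example

```r
library(curp)

params <- curp_params(prob_resource = 0.5, min_energy = 0.5, seed = 1)
trace  <- run_simulation(params, n_generations = 1000, record = "generation")
tail(as.data.frame(trace), 3)
#>      run_id generation period mean_given_energy mean_correlation
#> 998   run_1        998   9980        0.04143037        0.4061772
#> 999   run_1        999   9990        0.04536874        0.3845848
#> 1000  run_1       1000  10000        0.03937613        0.3791927
```

Each row is one generation's population mean of the two heritable
traits. This particular run has just fallen off the cooperative state
(mean donation fraction near zero) while partner choice is still biased
toward generous recipients (mean correlation ≈ +0.38) — at this
moderate-stress setting the coordinated state is metastable and
replicates alternate between surplus-sharing episodes near
`given_energy ≈ 1 − min_energy = 0.5` and collapses. Replicated runs
summarise the cell:

```r
reps <- lapply(1:5, function(r) {
  p <- curp_params(prob_resource = 0.5, min_energy = 0.5,
                   seed = derive_seed(1, r))
  run_simulation(p, 1000, record = "generation")
})
regime_summary(reps, min_energy = 0.5)
#> <curp_regime> intermediate (min_energy = 0.50, 5 replicates)
#>   mean given_energy 0.371, mean correlation 0.196
#>   temporal var(g) 0.0166, dispersion(final) 0.1605
```

The pooled post-burn-in mean donation fraction (0.371) sits below the
surplus norm 0.5 because the average mixes coordinated and collapsed
episodes; the positive mean correlation is the indirect-reciprocity
signature. `kde_state_space()` turns the same pooled records into a
density over the strategy space, and `grid_design()` + `run_batch()`
reproduce the full 7×7 resource-pressure sweep.

For the sensitivity screen:

```r
design <- lhs_design(200, lhs_ranges("desk"), generations = 150,
                     master_seed = 1)
batch  <- run_batch(design)
importance_from_batch(design, batch$traces)   # RF(800, 5) on the PCA response
```

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/curp.R run  --config cfg.yaml --seed 1 --out out/
Rscript inst/cli/curp.R lhs  --n 200 --scale desk --out screen/
Rscript inst/cli/curp.R grid --preset smoke --out sweep/
Rscript inst/cli/curp.R analyze importance --design screen/design.csv \
        --traces screen --out screen/analysis
```

Configs are flat YAML files with the hyphenated parameter names
(`n-people`, `prob-resource`, `min-energy`, ...) plus `seed` and
`generations`.

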