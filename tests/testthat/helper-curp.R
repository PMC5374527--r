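# Shared fixtures, built in code.

make_agents <- function(given_energy, correlation = rep(0, length(given_energy)),
                        energy = rep(0, length(given_energy)),
                        fitness = rep(0L, length(given_energy)),
                        lucky = rep(FALSE, length(given_energy))) {
  data.frame(given_energy = given_energy, correlation = correlation,
             energy = energy, fitness = as.integer(fitness), lucky = lucky)
}

# A synthetic trace in the package's long format.
make_trace <- function(mean_g, mean_c, run_id = "synth", rpg = 10) {
  n <- length(mean_g)
  structure(
    data.frame(run_id = run_id, generation = seq_len(n),
               period = seq_len(n) * rpg,
               mean_given_energy = mean_g, mean_correlation = mean_c),
    class = c("curp_trace", "data.frame"))
}

# Closed-form donee-selection law: tournament = whole pool (fraction 1).
# P(i) = |c| * [i extreme]/n_ties + (1 - |c|)/m
mixture_probs <- function(pool_g, corr) {
  m <- length(pool_g)
  extreme <- if (corr > 0) pool_g == max(pool_g) else pool_g == min(pool_g)
  p_unif <- rep(1 / m, m)
  if (corr == 0) return(p_unif)
  abs(corr) * extreme / sum(extreme) + (1 - abs(corr)) * p_unif
}

desk_params <- function(...) {
  curp_params(n_people = 100, rounds_per_generation = 10, ...)
}
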