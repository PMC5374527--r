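with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Run a complete simulation
#'
#' Executes `n_generations` generations of `rounds_per_generation` periods
#' each. Every period consists of a stochastic resource draw, a sharing
#' phase, and a fitness update; at each generation boundary strategies
#' evolve by fitness-biased imitation plus mutation. The population means of
#' the two strategy variables are recorded for every period (they are
#' constant within a generation, so `record = "generation"` stores one row
#' per generation instead, a 1:`rounds_per_generation` compression).
#'
#' Runs are fully reproducible: the same `(params, seed)` pair yields an
#' identical trace. The caller's RNG state is left untouched when a seed is
#' supplied.
#'
#' @param params A [curp_params()] object; `params$seed` (if set) seeds the
#'   run.
#' @param n_generations Number of generations to simulate.
#' @param record `"period"` (default) or `"generation"` granularity.
#' @param run_id Identifier stored in the trace's `run_id` column.
#' @return A `curp_trace` data frame with columns `run_id`, `generation`,
#'   `period`, `mean_given_energy`, `mean_correlation`, and attributes
#'   `params`, `n_generations`, and `final_strategies` (the strategy pairs
#'   at the end of the run).
#' @examples
#' p <- curp_params(n_people = 50, seed = 1)
#' tr <- run_simulation(p, n_generations = 20)
#' head(tr)
#' @export
run_simulation <- function(params, n_generations,
                           record = c("period", "generation"),
                           run_id = "run_1") {
  params <- validate_params(params)
  record <- match.arg(record)
  stopifnot(length(n_generations) == 1L, n_generations >= 1)
  n_generations <- as.integer(n_generations)

  res <- with_optional_seed(params$seed, {
    pop <- init_population(params)
    cpp_run_simulation(
      pop$given_energy, pop$correlation,
      params$prob_resource, params$min_energy,
      params$sharing_tournament_size, params$strategy_tournament_size,
      params$prob_mutation, params$rounds_per_generation, n_generations
    )
  })

  rpg <- params$rounds_per_generation
  if (record == "period") {
    gen <- rep(seq_len(n_generations), each = rpg)
    trace <- data.frame(
      run_id = run_id,
      generation = gen,
      period = seq_len(n_generations * rpg),
      mean_given_energy = rep(res$mean_given_energy, each = rpg),
      mean_correlation = rep(res$mean_correlation, each = rpg)
    )
  } else {
    trace <- data.frame(
      run_id = run_id,
      generation = seq_len(n_generations),
      period = seq_len(n_generations) * rpg,
      mean_given_energy = res$mean_given_energy,
      mean_correlation = res$mean_correlation
    )
  }
  attr(trace, "params") <- params
  attr(trace, "n_generations") <- n_generations
  attr(trace, "final_strategies") <- data.frame(
    given_energy = res$final_given_energy,
    correlation = res$final_correlation
  )
  class(trace) <- c("curp_trace", "data.frame")
  trace
}

#' Aggregate a per-period trace to one row per generation
#'
#' @param trace A `curp_trace` data frame.
#' @return The trace with one row per generation (`period` is the last
#'   period of each generation).
#' @export
trace_by_generation <- function(trace) {
  if (!all(c("generation", "period") %in% names(trace)))
    stop("not a simulation trace", call. = FALSE)
  keep <- !duplicated(trace$generation, fromLast = TRUE)
  out <- trace[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop burn-in records from a trace
#'
#' @param trace A `curp_trace` data frame.
#' @param burn_in Number of initial periods to discard; `NULL` discards the
#'   first 20% of the run.
#' @return The post-burn-in records.
#' @export
trace_after_burn_in <- function(trace, burn_in = NULL) {
  if (is.null(burn_in)) burn_in <- 0.2 * max(trace$period)
  out <- trace[trace$period > burn_in, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("burn_in removes every record of the trace", call. = FALSE)
  rownames(out) <- NULL
  out
}
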