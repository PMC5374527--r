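#' Create the initial population
#'
#' Agents start with strategies drawn uniformly from the full strategy space
#' (`given_energy` on `[0, 1]`, `correlation` on `[-1, 1]`) — the same
#' distribution mutation draws from — with zero energy and zero fitness.
#' Uses the current R random stream; call `set.seed()` (or use
#' [run_simulation()], which seeds from `params$seed`) for reproducibility.
#'
#' @param params A [curp_params()] object.
#' @return A data frame with one row per agent and columns `given_energy`,
#'   `correlation`, `energy`, `fitness`, `lucky`.
#' @export
init_population <- function(params) {
  params <- validate_params(params)
  n <- params$n_people
  data.frame(
    given_energy = runif(n),
    correlation = runif(n, -1, 1),
    energy = numeric(n),
    fitness = integer(n),
    lucky = logical(n)
  )
}

#' Draw resources for one period
#'
#' Each agent independently acquires one unit of energy with probability
#' `prob_resource`; all other energies are reset to zero (there is no
#' storage across periods).
#'
#' @param agents Population data frame from [init_population()].
#' @param prob_resource Acquisition probability in `[0, 1]`.
#' @return The population with `energy` set to 0/1 and the logical `lucky`
#'   column marking agents that drew a unit.
#' @export
draw_resources <- function(agents, prob_resource) {
  agents$lucky <- runif(nrow(agents)) < prob_resource
  agents$energy <- as.numeric(agents$lucky)
  agents
}

#' Recipients currently eligible for a donation
#'
#' An agent can receive donations while it did not draw a resource unit this
#' period and its accumulated energy is still at or below the survival
#' threshold; once strictly above `min_energy` it is sated and receives no
#' more.
#'
#' @param agents Population data frame (mid sharing phase).
#' @param min_energy Survival threshold.
#' @return Integer row indices of the eligible recipients.
#' @export
eligible_donees <- function(agents, min_energy) {
  which(!agents$lucky & agents$energy <= min_energy)
}

#' Select a donee from a pool of eligible recipients
#'
#' The donor samples a tournament of `ceiling(frac * length(pool))`
#' candidates (at least one) without replacement. With probability equal to
#' the absolute value of its `correlation` it picks the extreme candidate —
#' the most generous (highest `given_energy`) when correlation is positive,
#' the least generous when negative — and otherwise a uniform-random
#' candidate. Ties in generosity are broken uniformly at random.
#'
#' @param agents Population data frame.
#' @param donor Row index of the donor (supplies its `correlation`).
#' @param pool Integer row indices of eligible recipients (must not include
#'   the donor).
#' @param sharing_tournament_size Tournament fraction of the pool.
#' @return The chosen recipient's row index, or `NA_integer_` if the pool is
#'   empty.
#' @export
select_donee <- function(agents, donor, pool, sharing_tournament_size) {
  if (length(pool) == 0L) return(NA_integer_)
  j <- cpp_select_donee(agents$correlation[donor],
                        agents$given_energy[pool],
                        sharing_tournament_size)
  pool[j]
}

#' Run one sharing phase
#'
#' Lucky agents act once each in a fresh uniform-random order. Each donor
#' transfers `given_energy` of its unit to a donee selected as in
#' [select_donee()]; the recipient pool is recomputed before every donor
#' acts (asynchronous update), so an agent pushed strictly above
#' `min_energy` stops receiving immediately. Total energy is conserved.
#'
#' @param agents Population data frame after [draw_resources()].
#' @param params A [curp_params()] object (uses `min_energy` and
#'   `sharing_tournament_size`).
#' @return The population with post-sharing energies.
#' @export
sharing_phase <- function(agents, params) {
  agents$energy <- cpp_sharing_phase(
    agents$given_energy, agents$correlation, agents$energy,
    as.integer(agents$lucky), params$min_energy,
    params$sharing_tournament_size
  )
  agents
}

#' Update fitness at the end of a period
#'
#' Each agent whose energy strictly exceeds `min_energy` survives the period
#' and gains one fitness unit; energy exactly at the threshold counts as
#' starvation. Energies (and the lucky flags) are then reset for the next
#' period.
#'
#' @param agents Population data frame after [sharing_phase()].
#' @param min_energy Survival threshold.
#' @return The population with updated `fitness` and reset `energy`.
#' @export
fitness_update <- function(agents, min_energy) {
  agents$fitness <- agents$fitness + as.integer(agents$energy > min_energy)
  agents$energy <- 0
  agents$lucky <- FALSE
  agents
}

#' Evolve strategies at a generation boundary
#'
#' In a fresh random order each agent samples
#' `ceiling(strategy_tournament_size * n_people)` other agents (never
#' itself) without replacement and copies the strategy of the sampled agent
#' with the highest fitness — ties broken uniformly — but only if that
#' fitness strictly exceeds its own. Updates are asynchronous: a copied
#' strategy may itself have been updated earlier in the same boundary.
#' Afterwards every agent independently mutates with probability
#' `prob_mutation`, replacing its strategy by a uniform draw from the
#' strategy space, and all fitnesses are reset to zero.
#'
#' @param agents Population data frame at the end of a generation.
#' @param params A [curp_params()] object.
#' @return The population with next-generation strategies and zero fitness.
#' @export
evolve_generation <- function(agents, params) {
  res <- cpp_evolve_generation(
    agents$given_energy, agents$correlation, agents$fitness,
    params$strategy_tournament_size, params$prob_mutation
  )
  agents$given_energy <- res$given_energy
  agents$correlation <- res$correlation
  agents$fitness <- 0L
  agents
}
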