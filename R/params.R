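#' Model parameters
#'
#' Bundles the seven study parameters of the sharing model plus an optional
#' random seed into a validated `curp_params` object. Defaults follow the
#' resource-pressure grid parameterisation (population of 300, tournament
#' fractions of 1%, mutation probability 0.01, ten rounds per generation),
#' with moderate resource pressure (`prob_resource = 0.5`,
#' `min_energy = 0.5`).
#'
#' @param n_people Number of agents; constant for a whole run.
#' @param prob_resource Per-period probability that an agent acquires one
#'   resource unit, in `[0, 1]`.
#' @param min_energy Survival threshold as a fraction of the resource unit,
#'   in `[0, 1]`. An agent starves in a period unless its energy strictly
#'   exceeds this value.
#' @param sharing_tournament_size Fraction (in `(0, 1]`; 0 is accepted and
#'   behaves like the minimum tournament of one) of the currently eligible
#'   recipients a donor samples when choosing a donee.
#' @param strategy_tournament_size Fraction of the population an agent
#'   samples in the imitation step, in `(0, 1]`.
#' @param prob_mutation Probability that an agent replaces its strategy by a
#'   uniform draw from the strategy space at a generation boundary.
#' @param rounds_per_generation Number of periods between strategy updates.
#' @param seed Optional integer seed; [run_simulation()] uses it for full
#'   reproducibility.
#'
#' @return A list of class `curp_params`.
#' @examples
#' p <- curp_params(n_people = 50, prob_resource = 0.8)
#' p$n_people
#' @export
curp_params <- function(n_people = 300L,
                        prob_resource = 0.5,
                        min_energy = 0.5,
                        sharing_tournament_size = 0.01,
                        strategy_tournament_size = 0.01,
                        prob_mutation = 0.01,
                        rounds_per_generation = 10L,
                        seed = NULL) {
  p <- list(
    n_people = n_people,
    prob_resource = as.numeric(prob_resource),
    min_energy = as.numeric(min_energy),
    sharing_tournament_size = as.numeric(sharing_tournament_size),
    strategy_tournament_size = as.numeric(strategy_tournament_size),
    prob_mutation = as.numeric(prob_mutation),
    rounds_per_generation = rounds_per_generation,
    seed = seed
  )
  class(p) <- "curp_params"
  p <- validate_params(p)
  p$n_people <- as.integer(p$n_people)
  p$rounds_per_generation <- as.integer(p$rounds_per_generation)
  if (!is.null(p$seed)) p$seed <- as.integer(p$seed)
  p
}

check_scalar <- function(value, name, lo, hi, integer = FALSE) {
  if (length(value) != 1L || !is.numeric(value) || is.na(value))
    stop(sprintf("`%s` must be a single non-missing number", name),
         call. = FALSE)
  if (integer && value != as.integer(value))
    stop(sprintf("`%s` must be an integer", name), call. = FALSE)
  if (value < lo || value > hi)
    stop(sprintf("`%s` must lie in [%s, %s] (got %s)", name,
                 format(lo), format(hi), format(value)), call. = FALSE)
  invisible(value)
}

#' Validate a `curp_params` object
#'
#' Checks every field against its admissible interval and errors naming the
#' offending field.
#'
#' @param params A `curp_params` object (or a bare list with the same
#'   fields).
#' @return `params`, invisibly classed as `curp_params`.
#' @export
validate_params <- function(params) {
  check_scalar(params$n_people, "n_people", 1, .Machine$integer.max,
               integer = TRUE)
  check_scalar(params$prob_resource, "prob_resource", 0, 1)
  check_scalar(params$min_energy, "min_energy", 0, 1)
  check_scalar(params$sharing_tournament_size, "sharing_tournament_size",
               0, 1)
  check_scalar(params$strategy_tournament_size, "strategy_tournament_size",
               0, 1)
  check_scalar(params$prob_mutation, "prob_mutation", 0, 1)
  check_scalar(params$rounds_per_generation, "rounds_per_generation",
               1, .Machine$integer.max, integer = TRUE)
  if (!is.null(params$seed))
    check_scalar(params$seed, "seed", -.Machine$integer.max,
                 .Machine$integer.max, integer = TRUE)
  class(params) <- "curp_params"
  invisible(params)
}

#' @export
print.curp_params <- function(x, ...) {
  cat("<curp_params>\n")
  for (nm in setdiff(names(x), "seed"))
    cat(sprintf("  %-25s %s\n", nm, format(x[[nm]])))
  cat(sprintf("  %-25s %s\n", "seed",
              if (is.null(x$seed)) "<unset>" else format(x$seed)))
  invisible(x)
}
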