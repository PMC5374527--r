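CONFIG_KEYS <- c(
  "n-people" = "n_people",
  "prob-resource" = "prob_resource",
  "min-energy" = "min_energy",
  "sharing-tournament-size" = "sharing_tournament_size",
  "strategy-tournament-size" = "strategy_tournament_size",
  "prob-mutation" = "prob_mutation",
  "rounds-per-generation" = "rounds_per_generation",
  "seed" = "seed",
  "generations" = "generations"
)

#' Load a run configuration
#'
#' Reads a flat YAML file whose keys are the hyphenated study-parameter
#' names (`n-people`, `prob-resource`, `min-energy`,
#' `sharing-tournament-size`, `strategy-tournament-size`, `prob-mutation`,
#' `rounds-per-generation`) plus `seed` and `generations`. Underscored
#' spellings are accepted too. Omitted keys fall back to the
#' [curp_params()] defaults with `seed = 1` and `generations = 1000`; an
#' empty file yields the all-default configuration with a warning. Unknown
#' keys and out-of-range values raise an error naming the key.
#'
#' @param path Path to the YAML file.
#' @return A `curp_config` list: `params` (a [curp_params()] object) and
#'   `generations`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw) || length(raw) == 0L) {
    warning("empty config file; using defaults", call. = FALSE)
    raw <- list()
  }
  names(raw) <- gsub("_", "-", names(raw))
  unknown <- setdiff(names(raw), names(CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  vals <- stats::setNames(raw, CONFIG_KEYS[names(raw)])
  defaults <- list(seed = 1L, generations = 1000L)
  get_val <- function(nm, fallback) {
    if (!is.null(vals[[nm]])) vals[[nm]] else fallback
  }
  params <- curp_params(
    n_people = get_val("n_people", 300L),
    prob_resource = get_val("prob_resource", 0.5),
    min_energy = get_val("min_energy", 0.5),
    sharing_tournament_size = get_val("sharing_tournament_size", 0.01),
    strategy_tournament_size = get_val("strategy_tournament_size", 0.01),
    prob_mutation = get_val("prob_mutation", 0.01),
    rounds_per_generation = get_val("rounds_per_generation", 10L),
    seed = get_val("seed", defaults$seed)
  )
  generations <- get_val("generations", defaults$generations)
  check_scalar(generations, "generations", 1, .Machine$integer.max,
               integer = TRUE)
  structure(list(params = params, generations = as.integer(generations)),
            class = "curp_config")
}

#' Write a run configuration
#'
#' Serializes a `curp_config` with the hyphenated key spelling, so
#' `load_config(write_config(cfg, path))` round-trips losslessly.
#'
#' @param config A `curp_config` list (from [load_config()] or built from
#'   [curp_params()]).
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  p <- config$params
  out <- list(
    "n-people" = p$n_people,
    "prob-resource" = p$prob_resource,
    "min-energy" = p$min_energy,
    "sharing-tournament-size" = p$sharing_tournament_size,
    "strategy-tournament-size" = p$strategy_tournament_size,
    "prob-mutation" = p$prob_mutation,
    "rounds-per-generation" = p$rounds_per_generation,
    "seed" = if (is.null(p$seed)) 1L else p$seed,
    "generations" = config$generations
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
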