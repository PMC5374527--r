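PARAM_COLS <- c("n_people", "prob_resource", "min_energy",
                "sharing_tournament_size", "strategy_tournament_size",
                "prob_mutation", "rounds_per_generation")

INTEGER_PARAMS <- c("n_people", "rounds_per_generation")

#' Parameter ranges for Latin Hypercube screening
#'
#' The `"paper"` scale returns the published screening ranges; `"desk"`
#' caps the population at 200 agents so a 200-point screen runs on a
#' single core in minutes, leaving every other range untouched.
#'
#' @param scale `"paper"` or `"desk"`.
#' @return Named list of `c(lo, hi)` ranges over the seven study
#'   parameters.
#' @export
lhs_ranges <- function(scale = c("paper", "desk")) {
  scale <- match.arg(scale)
  r <- list(
    n_people = c(100, 500),
    prob_resource = c(0, 1),
    min_energy = c(0, 1),
    sharing_tournament_size = c(0, 1),
    strategy_tournament_size = c(0.01, 1),
    prob_mutation = c(0.01, 1),
    rounds_per_generation = c(10, 50)
  )
  if (scale == "desk") r$n_people <- c(100, 200)
  r
}

#' Derive a per-run seed from a master seed
#'
#' A splittable linear scheme modulo the Mersenne prime `2^31 - 1`: seeds
#' are distinct across run indices for any fixed master seed (the index
#' multiplier is coprime to the modulus) and each run can be re-executed in
#' isolation, so batch results do not depend on execution order.
#'
#' @param master_seed Integer master seed.
#' @param index Run index (1-based).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647
  as.integer(((master_seed %% m) * 48271 + (index %% m) * 279470273) %% m)
}

#' Latin Hypercube experiment design
#'
#' Divides each parameter range into `n_points` equal-width strata and
#' places exactly one jittered sample per stratum per parameter
#' ([lhs::randomLHS]), with independent column permutations. Integer
#' parameters (`n_people`, `rounds_per_generation`) are rounded to the
#' nearest integer after sampling. A degenerate range (`lo == hi`) yields a
#' constant column with a warning.
#'
#' @param n_points Number of design points (the published screen uses
#'   3000).
#' @param ranges Ranges from [lhs_ranges()] (possibly modified).
#' @param generations Generations per run (published screen: 5000).
#' @param master_seed Master seed; per-run seeds come from [derive_seed()].
#' @return A `curp_design` data frame: `run_id`, the seven parameter
#'   columns, `generations`, `seed`.
#' @examples
#' d <- lhs_design(10, lhs_ranges("desk"), generations = 50, master_seed = 1)
#' nrow(d)
#' @export
lhs_design <- function(n_points, ranges = lhs_ranges("paper"),
                       generations = 5000, master_seed = 1) {
  stopifnot(n_points >= 1)
  missing_par <- setdiff(PARAM_COLS, names(ranges))
  if (length(missing_par))
    stop("ranges missing parameter(s): ", paste(missing_par, collapse = ", "),
         call. = FALSE)
  u <- with_optional_seed(master_seed,
                          lhs::randomLHS(as.integer(n_points),
                                         length(PARAM_COLS)))
  design <- data.frame(run_id = sprintf("lhs_%04d", seq_len(n_points)))
  for (j in seq_along(PARAM_COLS)) {
    nm <- PARAM_COLS[j]
    lo <- ranges[[nm]][1]; hi <- ranges[[nm]][2]
    if (lo == hi)
      warning(sprintf("degenerate range for `%s`: constant column", nm),
              call. = FALSE)
    val <- lo + u[, j] * (hi - lo)
    if (nm %in% INTEGER_PARAMS) val <- round(val)
    design[[nm]] <- val
  }
  design$generations <- as.integer(generations)
  design$seed <- vapply(seq_len(n_points), derive_seed,
                        integer(1), master_seed = master_seed)
  class(design) <- c("curp_design", "data.frame")
  attr(design, "kind") <- "lhs"
  attr(design, "master_seed") <- master_seed
  design
}

#' Resource-pressure grid design
#'
#' Full Cartesian product of `prob_resource` and `min_energy` values with
#' replicated runs per cell. Defaults reproduce the published sweep: both
#' axes `seq(0.2, 0.8, by = 0.1)` (a 7x7 grid), 30 replicates, population
#' of 300, ten rounds per generation, mutation probability 0.01, both
#' tournament fractions 0.01, 5000 generations — 1470 runs in total.
#'
#' @param p_values,e_values Grid values for `prob_resource` / `min_energy`.
#' @param replicates Replicates per cell.
#' @param generations Generations per run.
#' @param fixed A [curp_params()] object supplying the remaining
#'   parameters.
#' @param master_seed Master seed; per-run seeds come from [derive_seed()].
#' @return A `curp_design` data frame with one row per run, including
#'   `replicate` and cell coordinates.
#' @examples
#' nrow(grid_design())  # 1470
#' @export
grid_design <- function(p_values = seq(0.2, 0.8, by = 0.1),
                        e_values = seq(0.2, 0.8, by = 0.1),
                        replicates = 30,
                        generations = 5000,
                        fixed = curp_params(),
                        master_seed = 1) {
  stopifnot(length(p_values) >= 1, length(e_values) >= 1, replicates >= 1)
  cells <- expand.grid(prob_resource = p_values, min_energy = e_values,
                       replicate = seq_len(replicates),
                       KEEP.OUT.ATTRS = FALSE)
  n <- nrow(cells)
  design <- data.frame(
    run_id = sprintf("grid_p%0.2f_e%0.2f_r%02d", cells$prob_resource,
                     cells$min_energy, cells$replicate),
    n_people = fixed$n_people,
    prob_resource = cells$prob_resource,
    min_energy = cells$min_energy,
    sharing_tournament_size = fixed$sharing_tournament_size,
    strategy_tournament_size = fixed$strategy_tournament_size,
    prob_mutation = fixed$prob_mutation,
    rounds_per_generation = fixed$rounds_per_generation,
    generations = as.integer(generations),
    seed = vapply(seq_len(n), derive_seed, integer(1),
                  master_seed = master_seed),
    replicate = cells$replicate
  )
  class(design) <- c("curp_design", "data.frame")
  attr(design, "kind") <- "grid"
  attr(design, "master_seed") <- master_seed
  design
}

params_from_design_row <- function(row) {
  curp_params(
    n_people = row$n_people,
    prob_resource = row$prob_resource,
    min_energy = row$min_energy,
    sharing_tournament_size = row$sharing_tournament_size,
    strategy_tournament_size = row$strategy_tournament_size,
    prob_mutation = row$prob_mutation,
    rounds_per_generation = row$rounds_per_generation,
    seed = row$seed
  )
}

run_one <- function(row, record) {
  run_simulation(params_from_design_row(row), row$generations,
                 record = record, run_id = row$run_id)
}

#' Execute an experiment design
#'
#' Runs every row of a design. Each run is seeded independently
#' ([derive_seed()]), so results are identical whatever the worker count or
#' execution order. When `out_dir` is given each finished trace is written
#' to `out_dir/traces/<run_id>.csv` as it completes and existing trace
#' files are reused (`status = "cached"`), so an interrupted batch resumes
#' where it stopped. A failing run is recorded in the manifest and the
#' batch continues.
#'
#' @param design A `curp_design` data frame.
#' @param record Trace granularity, `"generation"` (default, compact) or
#'   `"period"`.
#' @param out_dir Optional checkpoint/output directory.
#' @param workers Number of forked workers ([parallel::mclapply]); 1 runs
#'   serially.
#' @param progress Print a line per completed run.
#' @return A list with `traces` (named list of `curp_trace`s; `NULL` for
#'   failed runs) and `manifest` (data frame `run_id`, `status`, `error`).
#' @export
run_batch <- function(design, record = c("generation", "period"),
                      out_dir = NULL, workers = 1L, progress = FALSE) {
  record <- match.arg(record)
  if (!is.null(out_dir))
    dir.create(file.path(out_dir, "traces"), recursive = TRUE,
               showWarnings = FALSE)
  one <- function(i) {
    row <- design[i, , drop = FALSE]
    trace_file <- if (is.null(out_dir)) NULL else
      file.path(out_dir, "traces", paste0(row$run_id, ".csv"))
    if (!is.null(trace_file) && file.exists(trace_file))
      return(list(trace = read_trace(trace_file), status = "cached",
                  error = NA_character_))
    res <- tryCatch({
      tr <- run_one(row, record)
      if (!is.null(trace_file)) write_trace(tr, trace_file)
      list(trace = tr, status = "ok", error = NA_character_)
    }, error = function(e) {
      list(trace = NULL, status = "failed", error = conditionMessage(e))
    })
    if (progress)
      message(sprintf("[%d/%d] %s: %s", i, nrow(design), row$run_id,
                      res$status))
    res
  }
  results <- if (workers > 1L) {
    parallel::mclapply(seq_len(nrow(design)), one, mc.cores = workers)
  } else {
    lapply(seq_len(nrow(design)), one)
  }
  traces <- lapply(results, `[[`, "trace")
  names(traces) <- design$run_id
  manifest <- data.frame(
    run_id = design$run_id,
    status = vapply(results, `[[`, character(1), "status"),
    error = vapply(results, `[[`, character(1), "error")
  )
  list(traces = traces, manifest = manifest)
}
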