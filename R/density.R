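as_trace_list <- function(traces) {
  if (is.data.frame(traces)) traces <- list(traces)
  traces <- traces[!vapply(traces, is.null, logical(1))]
  if (length(traces) == 0L) stop("no traces supplied", call. = FALSE)
  traces
}

#' Kernel density estimate of the strategy state space
#'
#' Pools the post-burn-in `(mean_given_energy, mean_correlation)` records
#' of one grid cell's replicates and estimates their joint density with an
#' axis-aligned Gaussian kernel on a regular lattice over
#' `[0, 1] x [-1, 1]`. Bandwidths follow Scott's plug-in rule
#' (`sd * n^(-1/6)` per axis) and are recorded in the result; the density
#' is renormalized to integrate to one over the lattice. If the pooled
#' points are (numerically) all identical the estimate degenerates and a
#' point-mass record is returned instead of a division by a zero
#' bandwidth.
#'
#' @param traces One `curp_trace` or a list of them (a cell's replicates).
#' @param burn_in Periods to discard per trace; `NULL` = first 20% of each
#'   run (the published sweep discards 10,000 of 50,000 periods).
#' @param gridsize Lattice points per axis.
#' @param lims Lattice limits `c(g_lo, g_hi, c_lo, c_hi)`.
#' @return A `curp_density` list: `given_energy`, `correlation` (lattice
#'   axes), `density` (matrix), `bandwidth`, `n_points`, `point_mass`, and
#'   for the degenerate case `location`.
#' @export
kde_state_space <- function(traces, burn_in = NULL, gridsize = 51,
                            lims = c(0, 1, -1, 1)) {
  traces <- as_trace_list(traces)
  post <- do.call(rbind, lapply(traces, trace_after_burn_in,
                                burn_in = burn_in))
  x <- post$mean_given_energy
  y <- post$mean_correlation
  n <- length(x)
  sds <- c(sd(x), sd(y))
  if (any(sds < 1e-10)) {
    return(structure(list(point_mass = TRUE,
                          location = c(given_energy = mean(x),
                                       correlation = mean(y)),
                          n_points = n),
                     class = "curp_density"))
  }
  bw <- sds * n^(-1 / 6)  # Scott's rule, d = 2
  # kde2d uses h/4 as the Gaussian sd, so pass 4x the plug-in bandwidth
  kd <- MASS::kde2d(x, y, h = 4 * bw, n = gridsize, lims = lims)
  dx <- diff(kd$x[1:2]); dy <- diff(kd$y[1:2])
  z <- kd$z / (sum(kd$z) * dx * dy)
  structure(list(given_energy = kd$x, correlation = kd$y, density = z,
                 bandwidth = c(given_energy = bw[1], correlation = bw[2]),
                 n_points = n, point_mass = FALSE),
            class = "curp_density")
}

#' Location of the density mode
#'
#' @param density A `curp_density` object.
#' @return Named vector `c(given_energy, correlation)` of the lattice point
#'   with maximal density (the point-mass location in the degenerate
#'   case).
#' @export
density_mode <- function(density) {
  if (isTRUE(density$point_mass)) return(density$location)
  ij <- which(density$density == max(density$density), arr.ind = TRUE)[1, ]
  c(given_energy = density$given_energy[ij[1]],
    correlation = density$correlation[ij[2]])
}

#' Default regime-classification thresholds
#'
#' `var_high`: a replicate whose post-burn-in temporal variance of mean
#' `given_energy` exceeds this value is considered unstable (for
#' reference, a trace bouncing uniformly over `[0, 1]` has variance 1/12).
#' `coord_tol`: half-width of the band around `1 - min_energy` within
#' which the mean donation fraction counts as coordinated surplus-sharing.
#'
#' @return Named list of thresholds.
#' @export
regime_thresholds <- function() {
  list(var_high = 0.02, coord_tol = 0.15)
}

classify_regime <- function(mean_g, mean_c, var_g, min_energy, thr) {
  if (var_g > thr$var_high) return("high_stress")
  if (abs(mean_g - (1 - min_energy)) <= thr$coord_tol && mean_c > 0)
    return("intermediate")
  "low_stress"
}

#' Regime summary of one grid cell
#'
#' Quantifies the three qualitative dynamical regimes of the
#' resource-pressure sweep. Per replicate it computes the post-burn-in
#' temporal mean and variance of the two strategy means, the final mean
#' strategies, and a regime label: `high_stress` when the temporal
#' variance of mean `given_energy` exceeds `var_high` (unstable, constant
#' strategy turnover); otherwise `intermediate` when the mean donation
#' fraction lies within `coord_tol` of the surplus `1 - min_energy` and
#' the mean partner-choice bias is positive (coordinated indirect
#' reciprocity); otherwise `low_stress` (selection-free drift). The
#' cell-level label applies the same rule to the pooled statistics.
#'
#' @param traces One `curp_trace` or a list of replicates for the cell.
#' @param min_energy The cell's survival threshold.
#' @param burn_in Periods to discard per trace; `NULL` = first 20%.
#' @param thresholds See [regime_thresholds()].
#' @return A `curp_regime` list: `replicates` (per-replicate data frame
#'   with labels), pooled `mean_given_energy`, `mean_correlation`,
#'   `temporal_var_given_energy` (mean over replicates),
#'   `dispersion_final` and `dispersion_mean` (across-replicate sd of the
#'   final / time-averaged strategies, both axes combined), and `label`.
#' @export
regime_summary <- function(traces, min_energy, burn_in = NULL,
                           thresholds = regime_thresholds()) {
  traces <- as_trace_list(traces)
  reps <- do.call(rbind, lapply(seq_along(traces), function(i) {
    post <- trace_after_burn_in(traces[[i]], burn_in = burn_in)
    mg <- mean(post$mean_given_energy)
    mc <- mean(post$mean_correlation)
    vg <- if (nrow(post) > 1L) var(post$mean_given_energy) else 0
    data.frame(
      replicate = i,
      mean_given_energy = mg,
      mean_correlation = mc,
      temporal_var_given_energy = vg,
      temporal_var_correlation =
        if (nrow(post) > 1L) var(post$mean_correlation) else 0,
      final_given_energy = post$mean_given_energy[nrow(post)],
      final_correlation = post$mean_correlation[nrow(post)],
      label = classify_regime(mg, mc, vg, min_energy, thresholds)
    )
  }))
  disp <- function(a, b) {
    if (length(a) < 2L) return(0)
    sqrt(var(a) + var(b))
  }
  pooled_g <- mean(reps$mean_given_energy)
  pooled_c <- mean(reps$mean_correlation)
  pooled_v <- mean(reps$temporal_var_given_energy)
  structure(list(
    replicates = reps,
    min_energy = min_energy,
    mean_given_energy = pooled_g,
    mean_correlation = pooled_c,
    temporal_var_given_energy = pooled_v,
    dispersion_final = disp(reps$final_given_energy, reps$final_correlation),
    dispersion_mean = disp(reps$mean_given_energy, reps$mean_correlation),
    label = classify_regime(pooled_g, pooled_c, pooled_v, min_energy,
                            thresholds)
  ), class = "curp_regime")
}

#' @export
print.curp_regime <- function(x, ...) {
  cat(sprintf("<curp_regime> %s (min_energy = %.2f, %d replicates)\n",
              x$label, x$min_energy, nrow(x$replicates)))
  cat(sprintf("  mean given_energy %.3f, mean correlation %.3f\n",
              x$mean_given_energy, x$mean_correlation))
  cat(sprintf("  temporal var(g) %.4f, dispersion(final) %.4f\n",
              x$temporal_var_given_energy, x$dispersion_final))
  invisible(x)
}
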