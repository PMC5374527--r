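TRACE_COLS <- c("run_id", "generation", "period", "mean_given_energy",
                "mean_correlation")

#' Write a simulation trace as CSV
#'
#' Long format, UTF-8, '.' decimal separator, header `run_id, generation,
#' period, mean_given_energy, mean_correlation`.
#'
#' @param trace A `curp_trace` data frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace[, TRACE_COLS], path, row.names = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a simulation trace CSV
#'
#' @param path Path written by [write_trace()].
#' @return A `curp_trace` data frame.
#' @export
read_trace <- function(path) {
  tr <- read.csv(path, fileEncoding = "UTF-8")
  missing_col <- setdiff(TRACE_COLS, names(tr))
  if (length(missing_col))
    stop("trace file missing column(s): ",
         paste(missing_col, collapse = ", "), call. = FALSE)
  class(tr) <- c("curp_trace", "data.frame")
  tr
}

#' Write an experiment's outputs with a manifest
#'
#' Lays out `design.csv`, `traces/<run_id>.csv`, optional
#' `analysis/importance.csv` and `analysis/density_<cell>.csv`, and a
#' `manifest.json` recording the design's master seed, per-run status, the
#' package version, and an MD5 checksum per file. Re-running with
#' identical inputs reproduces identical files (the manifest carries no
#' timestamps).
#'
#' @param batch Result of [run_batch()].
#' @param design The `curp_design` that produced it.
#' @param out_dir Destination directory.
#' @param importance Optional `curp_importance` to store.
#' @param densities Optional named list of `curp_density` objects.
#' @param force Overwrite an existing non-empty directory.
#' @return The manifest list, invisibly.
#' @export
write_outputs <- function(batch, design, out_dir, importance = NULL,
                          densities = NULL, force = FALSE) {
  if (dir.exists(out_dir) &&
      length(setdiff(list.files(out_dir), "traces")) > 0 && !force)
    stop("output directory not empty (use force = TRUE): ", out_dir,
         call. = FALSE)
  dir.create(file.path(out_dir, "traces"), recursive = TRUE,
             showWarnings = FALSE)
  write.csv(as.data.frame(design), file.path(out_dir, "design.csv"),
            row.names = FALSE)
  for (id in names(batch$traces)) {
    if (!is.null(batch$traces[[id]]))
      write_trace(batch$traces[[id]],
                  file.path(out_dir, "traces", paste0(id, ".csv")))
  }
  if (!is.null(importance) || !is.null(densities))
    dir.create(file.path(out_dir, "analysis"), showWarnings = FALSE)
  if (!is.null(importance))
    write.csv(as.data.frame(importance),
              file.path(out_dir, "analysis", "importance.csv"),
              row.names = FALSE)
  for (cell in names(densities)) {
    d <- densities[[cell]]
    df <- if (isTRUE(d$point_mass)) {
      data.frame(given_energy = d$location[1], correlation = d$location[2],
                 density = Inf)
    } else {
      expand.grid(given_energy = d$given_energy,
                  correlation = d$correlation, KEEP.OUT.ATTRS = FALSE) |>
        cbind(density = as.vector(d$density))
    }
    write.csv(df, file.path(out_dir, "analysis",
                            paste0("density_", cell, ".csv")),
              row.names = FALSE)
  }
  files <- list.files(out_dir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  checksums <- as.list(tools::md5sum(file.path(out_dir, files)))
  names(checksums) <- files
  manifest <- list(
    master_seed = attr(design, "master_seed"),
    design_kind = attr(design, "kind"),
    n_runs = nrow(design),
    status = batch$manifest,
    package_version = as.character(utils::packageVersion("curp")),
    checksums = checksums
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
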