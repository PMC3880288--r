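# Run outputs: CSV time series, legacy-VTK volumetric fields, vessel edge
# list, JSON run manifest, and checkpointing.

#' Write a 3D field as ASCII legacy VTK
#'
#' Emits a `STRUCTURED_POINTS` dataset with one scalar array, readable by
#' standard VTK viewers.
#'
#' @param field a 3D array.
#' @param path output path (conventionally `.vtk`).
#' @param name scalar array name.
#' @param spacing lattice spacing (written into the header).
#' @return the path, invisibly.
#' @export
write_vtk_field <- function(field, path, name = "field", spacing = 1) {
  d <- dim(field)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# vtk DataFile Version 3.0",
    paste0(name, " volume"),
    "ASCII",
    "DATASET STRUCTURED_POINTS",
    paste("DIMENSIONS", d[1], d[2], d[3]),
    "ORIGIN 0 0 0",
    paste("SPACING", spacing, spacing, spacing),
    paste("POINT_DATA", prod(d)),
    paste0("SCALARS ", name, " double 1"),
    "LOOKUP_TABLE default"), con)
  # x fastest, matching R's column-major layout
  writeLines(formatC(as.vector(field), format = "g", digits = 9), con)
  invisible(path)
}

#' Write all run outputs
#'
#' Emits, under `outdir`: `timeseries.csv` (the per-step record),
#' `vessels.csv` (the final network edge list), one `field_<species>.vtk`
#' per continuum species, `final_state.rds` (a loadable checkpoint of the
#' final state) and `manifest.json` (configuration, seed, package version
#' and file checksums) which reproduces the run when fed back through
#' [run_from_manifest()].
#'
#' @param result a `sim_result` from [run_simulation()].
#' @param outdir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  stopifnot(inherits(result, "sim_result"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir,
                                call. = FALSE)
  paths <- c(timeseries = file.path(outdir, "timeseries.csv"),
             vessels = file.path(outdir, "vessels.csv"),
             state = file.path(outdir, "final_state.rds"))
  utils::write.csv(result$record, paths[["timeseries"]], row.names = FALSE)
  write_vessel_file(result$state$vessels, paths[["vessels"]])
  saveRDS(result$state, paths[["state"]])
  for (sp in names(result$state$fields)) {
    p <- file.path(outdir, paste0("field_", sp, ".vtk"))
    write_vtk_field(result$state$fields[[sp]], p, name = sp,
                    spacing = result$config$spacing_m)
    paths[[paste0("field_", sp)]] <- p
  }
  cfg <- unclass(result$config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  # doubles are stored as 17-significant-digit strings: JSON decimal output
  # is not guaranteed to round-trip the last ulp, and bitwise reproduction
  # of a run requires bitwise-identical parameters
  cfg <- lapply(cfg, function(v) {
    if (is.double(v)) ifelse(is.na(v), "NA", sprintf("%.17g", v)) else v
  })
  manifest <- list(
    package = "oncovasc",
    version = as.character(utils::packageVersion("oncovasc")),
    seed = result$config$rng_seed,
    config = cfg,
    checksums = as.list(tools::md5sum(unname(paths["timeseries"]))))
  mpath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths[["manifest"]] <- mpath
  invisible(paths)
}

#' Re-run a simulation from its manifest
#'
#' Reads the configuration embedded in a run manifest and repeats the run;
#' with an unchanged package this reproduces the recorded time series
#' exactly.
#'
#' @param manifest_path path to a `manifest.json` written by
#'   [write_outputs()].
#' @return a `sim_result`.
#' @export
run_from_manifest <- function(manifest_path) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  cfgl <- m$config
  cfgl$spacing_m <- NULL
  cfgl$dt_s <- NULL
  cfgl <- lapply(cfgl, function(v) {
    if (is.character(v) && length(v) == 1L) {
      if (identical(v, "NA")) return(NA_real_)
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) return(num)
    }
    v
  })
  cfg <- do.call(sim_config, cfgl)
  run_simulation(cfg)
}

#' Checkpoint / restore a simulation state
#'
#' @param state a `sim_state`.
#' @param path checkpoint file path.
#' @return `save_checkpoint()` the path invisibly; `load_checkpoint()` the
#'   restored `sim_state`.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(inherits(state, "sim_state"))
  state$rng_snapshot <- get(".Random.seed", envir = globalenv())
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!is.null(state$rng_snapshot)) {
    assign(".Random.seed", state$rng_snapshot, envir = globalenv())
    state$rng_snapshot <- NULL
  }
  state
}
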