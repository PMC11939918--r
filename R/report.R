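#' Default run configuration
#'
#' All tunable analysis parameters with their defaults, as a plain nested
#' list that serializes cleanly to JSON/YAML; used by the file-level entry
#' points and printable for provenance.
#'
#' @return A nested list of defaults.
#' @export
qcmd_default_config <- function() {
  k <- qcmd_constants()
  list(
    constants = list(f0_hz = k$f0_hz, sauerbrey_c = k$sauerbrey_c,
                     liquid = list(viscosity_pa_s = k$eta_l,
                                   density_g_cm3 = k$rho_l),
                     film_density_g_cm3 = k$rho_film),
    features = unclass(feature_params()),
    classify = list(slb_max_hz = 36, slv_min_hz = 50, slb_max_dd = 1.0),
    analysis_overtone = 7
  )
}

#' Simulate a preset and write the trace plus ground truth to files
#'
#' Writes the trace in the package CSV dialect and a JSON sidecar with the
#' generator's ground truth (noise-free frequency minimum/asymptote, areal
#' mass at the minimum, implied layer height, final coverages), for testing
#' downstream analyses against known answers.
#'
#' @param preset Preset name (see [scenario_presets()]) or a
#'   [simulation_config()].
#' @param out_prefix Output path prefix; writes `<prefix>.csv` and
#'   `<prefix>_truth.json`.
#' @param seed Optional seed override.
#' @return Named character vector of the two paths, invisibly.
#' @export
qcmd_simulate_files <- function(preset, out_prefix, seed = NULL) {
  config <- if (is.character(preset)) scenario_presets(preset) else preset
  stopifnot(inherits(config, "qcmd_sim_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  tr <- simulate_trace(config)
  paths <- c(trace = paste0(out_prefix, ".csv"),
             truth = paste0(out_prefix, "_truth.json"))
  write_qcmd_trace(tr, paths[["trace"]])
  jsonlite::write_json(attr(tr, "truth"), paths[["truth"]],
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Analyze trace files into a record table
#'
#' Reads each trace file, runs [summarize_experiment()] and collects one
#' record per trace. Per-file failures are reported and skipped; the
#' remaining files are still processed. Optionally writes the records as
#' CSV and per-trace phase-plot CSVs.
#'
#' @param paths Character vector of trace CSV paths (at least one).
#' @param out Optional path for the combined record CSV.
#' @param conditions Optional [experiment_conditions()] applied to every
#'   trace.
#' @param overtone Analysis overtone.
#' @param phase_dir Optional directory for phase-plot CSVs (dF, dD columns).
#' @param ... Passed to [summarize_experiment()].
#' @return A data frame of records (column `source` names the file), with
#'   attribute `errors` naming any failed files.
#' @export
qcmd_analyze_files <- function(paths, out = NULL, conditions = NULL,
                               overtone = 7, phase_dir = NULL, ...) {
  if (length(paths) == 0L) stop("usage: at least one trace path is required")
  recs <- list(); errs <- character()
  for (p in paths) {
    rec <- tryCatch({
      tr <- read_qcmd_trace(p)
      r <- summarize_experiment(tr, conditions = conditions,
                                overtone = overtone, ...)
      r$source <- basename(p)
      if (!is.null(phase_dir)) {
        dir.create(phase_dir, showWarnings = FALSE, recursive = TRUE)
        pp <- phase_plot(tr, overtone = overtone)
        utils::write.csv(pp, file.path(phase_dir,
                                       sub("\\.csv$", "_phase.csv",
                                           basename(p))),
                         row.names = FALSE)
      }
      r
    }, error = function(e) {
      errs[[length(errs) + 1L]] <<- paste0(p, ": ", conditionMessage(e))
      message("analysis failed for ", p, ": ", conditionMessage(e))
      NULL
    })
    if (!is.null(rec)) recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) stop("no trace could be analyzed")
  res <- do.call(rbind, recs)
  if (!is.null(out)) utils::write.csv(res, out, row.names = FALSE)
  attr(res, "errors") <- errs
  res
}

#' Emit the packaged reference tables and regenerated preset traces
#'
#' Copies the reference condition and feature tables into `dir` and
#' regenerates the four preset traces (with their ground-truth sidecars)
#' under their documented fixed seeds, so the emission is deterministic.
#'
#' @param dir Output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
qcmd_fixture_files <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(dir, mode = 2) != 0) stop("directory not writable: ", dir)
  written <- character()
  for (f in c("reference_conditions.csv", "reference_features.csv")) {
    src <- system.file("extdata", f, package = "qcmdfusion")
    dst <- file.path(dir, f)
    file.copy(src, dst, overwrite = TRUE)
    written <- c(written, dst)
  }
  for (nm in c("slb", "partial", "slv", "dopc_fig2")) {
    p <- qcmd_simulate_files(nm, file.path(dir, paste0("preset_", nm)))
    written <- c(written, p)
  }
  invisible(written)
}
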