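#' Write a run configuration with provenance
#'
#' Serializes parameters, seeds, and overrides as YAML next to the outputs
#' they generated, so any result can be regenerated from its manifest.
#'
#' @param config named list (parameters, seeds, scale factors).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  config$written_at <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  config$package_version <- as.character(utils::packageVersion("myelinwm"))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Read a run configuration
#'
#' @param path YAML file written by [write_run_config()] (unknown keys in
#'   hand-edited configs are reported as a hard error).
#' @param known optional character vector of allowed keys.
#' @return Named list.
#' @export
read_run_config <- function(path, known = NULL) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(known)) {
    bad <- setdiff(names(cfg), c(known, "written_at", "package_version"))
    if (length(bad)) {
      abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")))
    }
  }
  cfg
}

#' Write a spike raster as a two-column CSV
#'
#' @param trial a `drt_trial`.
#' @param path output CSV (`neuron`, `time_ms`; 0-based neuron ids).
#' @return `path`, invisibly.
#' @export
write_raster_csv <- function(trial, path) {
  utils::write.csv(trial$spikes, path, row.names = FALSE)
  invisible(path)
}

#' Read a spike raster CSV into a minimal trial object
#'
#' @param path CSV written by [write_raster_csv()].
#' @param params a [ring_params()] describing the task epochs.
#' @param cue_deg cue angle of the stored trial.
#' @return A `drt_trial`.
#' @export
read_raster_csv <- function(path, params, cue_deg) {
  sp <- utils::read.csv(path)
  structure(list(spikes = as_tibble(sp), cue_deg = cue_deg, seed = NA,
                 NE = params$NE, NI = params$NI,
                 fixation_ms = params$fixation_ms, cue_ms = params$cue_ms,
                 delay_ms = params$delay_ms,
                 t_total_ms = params$fixation_ms + params$cue_ms +
                   params$delay_ms),
            class = "drt_trial")
}
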