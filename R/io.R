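# Configuration and result I/O: YAML configs, CSV curves, JSON results and
# RDS persistence for ensembles and phantoms. Units on disk: mm, m/s, mL, s.

#' Write a configuration to YAML
#'
#' @param config an `acquisition_config`, `beam_config`, `spectral_config`
#'   or plain named list.
#' @param path output file.
#' @export
write_config_yaml <- function(config, path) {
  x <- unclass(config)
  x$.class <- class(config)[1]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a configuration written by [write_config_yaml()]
#'
#' @param path YAML file.
#' @return the configuration object with its class restored.
#' @export
read_config_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  cls <- x$.class
  x$.class <- NULL
  if (!is.null(cls) && cls != "list") class(x) <- cls
  x
}

#' Export an RVol result
#'
#' Writes the scalar results as JSON and the per-frame curves (frame time,
#' cross-sectional area, flow rate, jet depth) as CSV next to it.
#'
#' @param result an [estimate_rvol()] result.
#' @param json_path output JSON path.
#' @param csv_path optional CSV path for the curves.
#' @export
write_rvol_result <- function(result, json_path, csv_path = NULL) {
  out <- list(
    rvol_ml = result$rvol,
    feasible = result$feasible,
    infeasibility_reason = result$infeasibility_reason,
    jet_cross_sectional_area_mm2 = result$jet_cross_sectional_area,
    n_frames = length(result$frame_times),
    n_regurgitant_frames = length(result$phase_frames)
  )
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(
      frame_time_s = result$frame_times,
      jet_depth_mm = result$jet_depth_trace,
      area_mm2 = result$area_curve,
      flow_ml_s = result$flow_rate_curve
    ), csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Save / load an IQ ensemble
#'
#' RDS persistence for simulated ensembles (complex sample array, grids and
#' configurations in one self-describing object).
#'
#' @param ensemble an [simulate_iq()] ensemble.
#' @param path file path.
#' @export
save_ensemble <- function(ensemble, path) {
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname save_ensemble
#' @export
load_ensemble <- function(path) {
  x <- readRDS(path)
  stopifnot(inherits(x, "iq_ensemble"))
  x
}
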