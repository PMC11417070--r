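#' Read a study configuration file
#'
#' The configuration is a versioned YAML file carrying acquisition and
#' relaxation constants keyed by centre and field strength, input-function
#' model and parameters, fit options and statistics options. The packaged
#' default ([defaultStudyConfig()]) documents every entry.
#'
#' @param path path to a YAML study configuration.
#' @return a named list with class `studyConfig`.
#' @export
readStudyConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema_version))
    stop("config is missing schema_version")
  for (req in c("acquisition", "centres", "relaxation", "input_function"))
    if (is.null(cfg[[req]])) stop("config is missing section '", req, "'")
  class(cfg) <- c("studyConfig", "list")
  cfg
}

#' @rdname readStudyConfig
#' @export
defaultStudyConfig <- function() {
  readStudyConfig(system.file("extdata", "default_config.yaml",
                              package = "liverDCE", mustWork = TRUE))
}

#' Look up per-centre acquisition parameters
#'
#' @param config a study configuration list.
#' @param centre centre label (e.g. `"D"`).
#' @param fieldStrength tesla.
#' @return an [AcquisitionParams-class] for `lookupAcquisition()`, a
#'   [RelaxationParams-class] for `lookupRelaxation()`.
#' @export
lookupAcquisition <- function(config, centre, fieldStrength) {
  hit <- Filter(function(e) e$centre == centre &&
                  isTRUE(all.equal(e$field_strength_T, fieldStrength)),
                config$centres)
  if (length(hit) == 0)
    stop("no acquisition entry for centre ", centre, " at ",
         fieldStrength, " T")
  acq <- config$acquisition
  acquisitionParams(
    repetitionTime = acq$repetition_time_s,
    echoTime = acq$echo_time_s,
    flipAngle = hit[[1]]$flip_angle_deg,
    fieldStrength = fieldStrength,
    frameInterval = acq$frame_interval_s,
    nBaselineFrames = acq$n_baseline_frames)
}

#' @rdname lookupAcquisition
#' @export
lookupRelaxation <- function(config, fieldStrength) {
  hit <- Filter(function(e)
    isTRUE(all.equal(e$field_strength_T, fieldStrength)),
    config$relaxation)
  if (length(hit) == 0)
    stop("no relaxation entry for ", fieldStrength, " T")
  relaxationParams(
    r1BaselineLiver = hit[[1]]$r1_liver,
    relaxivityExtracellular = hit[[1]]$r_extracellular,
    relaxivityHepatocellular = hit[[1]]$r_hepatocellular)
}

#' @rdname lookupAcquisition
#' @param acq acquisition parameters; supplies the default injection start
#'   (end of the baseline window) when the config leaves it null.
#' @export
configInputFunction <- function(config, acq) {
  ifc <- config$input_function
  start <- ifc$injection_start_s
  if (is.null(start)) start <- acq@nBaselineFrames * acq@frameInterval
  inputFunctionParams(
    dose = ifc$dose_umol_kg,
    injectionStart = start,
    injectionDuration = ifc$injection_duration_s,
    distributionVolume = ifc$distribution_volume_ml_kg,
    bodyClearanceRate = ifc$body_clearance_rate_per_min,
    modelId = ifc$model_id)
}
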