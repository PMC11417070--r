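#' @import methods
#' @importFrom stats sd rnorm rlnorm aov oneway.test pairwise.t.test
#' @importFrom utils read.csv write.csv
NULL

#' Acquisition parameters of the spoiled gradient-echo sequence
#'
#' Holds the pulse-sequence constants needed by the signal model: repetition
#' time, echo time, flip angle, field strength, dynamic frame spacing and the
#' number of pre-contrast baseline frames. Times are in seconds, the flip
#' angle in degrees, the field strength in tesla. The echo time is carried as
#' metadata only: at TE of order 1 ms the T2* weighting is negligible and is
#' not modelled.
#'
#' @slot repetitionTime repetition time TR in seconds (> 0)
#' @slot echoTime echo time TE in seconds (metadata only)
#' @slot flipAngle flip angle in degrees, in (0, 90)
#' @slot fieldStrength main field strength in tesla
#' @slot frameInterval spacing of dynamic frames in seconds (> 0)
#' @slot nBaselineFrames number of pre-contrast frames (>= 1)
#'
#' @seealso [acquisitionParams()] for the user-facing constructor,
#'   [spgrSignal()] for the signal equation that consumes these.
#' @export
setClass("AcquisitionParams", representation(
  repetitionTime = "numeric",
  echoTime = "numeric",
  flipAngle = "numeric",
  fieldStrength = "numeric",
  frameInterval = "numeric",
  nBaselineFrames = "integer"
))

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@repetitionTime) != 1 || !is.finite(object@repetitionTime) ||
      object@repetitionTime <= 0)
    msg <- c(msg, "repetitionTime must be a single positive number (seconds)")
  if (length(object@flipAngle) != 1 || !is.finite(object@flipAngle) ||
      object@flipAngle <= 0 || object@flipAngle >= 90)
    msg <- c(msg, "flipAngle must lie strictly between 0 and 90 degrees")
  if (length(object@frameInterval) != 1 || object@frameInterval <= 0)
    msg <- c(msg, "frameInterval must be positive (seconds)")
  if (length(object@nBaselineFrames) != 1 || object@nBaselineFrames < 1L)
    msg <- c(msg, "nBaselineFrames must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' @param repetitionTime TR in seconds; the multi-centre rat protocol uses
#'   5.8 ms.
#' @param echoTime TE in seconds (1.1 ms in the protocol; not used by the
#'   T1-weighted signal model).
#' @param flipAngle excitation flip angle in degrees (20 or 30 depending on
#'   centre).
#' @param fieldStrength tesla (4.7 or 7).
#' @param frameInterval dynamic frame spacing in seconds.
#' @param nBaselineFrames number of pre-contrast frames used to anchor the
#'   signal scale.
#' @return an `AcquisitionParams` object.
#' @examples
#' acquisitionParams(flipAngle = 20, fieldStrength = 4.7)
#' @export
acquisitionParams <- function(repetitionTime = 5.8e-3, echoTime = 1.1e-3,
                              flipAngle = 20, fieldStrength = 4.7,
                              frameInterval = 5, nBaselineFrames = 10L) {
  new("AcquisitionParams", repetitionTime = repetitionTime,
      echoTime = echoTime, flipAngle = flipAngle,
      fieldStrength = fieldStrength, frameInterval = frameInterval,
      nBaselineFrames = as.integer(nBaselineFrames))
}

#' Relaxation parameters of the liver at a given field strength
#'
#' Pre-contrast longitudinal relaxation rate of liver tissue together with
#' gadoxetate relaxivities. The two tissue compartments see different
#' relaxivities: extracellular gadoxetate relaxes at the blood/interstitium
#' value while hepatocellular gadoxetate, partially bound to intracellular
#' proteins, relaxes faster.
#'
#' @slot r1BaselineLiver pre-contrast liver R1 in 1/s
#' @slot relaxivityExtracellular r1 of extracellular gadoxetate, 1/(mM s)
#' @slot relaxivityHepatocellular r1 of hepatocellular gadoxetate, 1/(mM s)
#' @export
setClass("RelaxationParams", representation(
  r1BaselineLiver = "numeric",
  relaxivityExtracellular = "numeric",
  relaxivityHepatocellular = "numeric"
))

setValidity("RelaxationParams", function(object) {
  v <- c(object@r1BaselineLiver, object@relaxivityExtracellular,
         object@relaxivityHepatocellular)
  if (length(v) != 3 || any(!is.finite(v)) || any(v <= 0))
    "r1BaselineLiver and both relaxivities must be single positive numbers"
  else TRUE
})

#' Construct relaxation parameters
#'
#' Defaults are field-strength-specific literature-style values for rat liver
#' and gadoxetate; see [defaultStudyConfig()] for the per-field table the
#' pipeline actually reads.
#'
#' @param r1BaselineLiver pre-contrast liver R1 (1/s)
#' @param relaxivityExtracellular extracellular gadoxetate relaxivity
#'   (1/mM/s)
#' @param relaxivityHepatocellular hepatocellular gadoxetate relaxivity
#'   (1/mM/s)
#' @return a `RelaxationParams` object.
#' @export
relaxationParams <- function(r1BaselineLiver = 1.0,
                             relaxivityExtracellular = 6.7,
                             relaxivityHepatocellular = 9.8) {
  new("RelaxationParams", r1BaselineLiver = r1BaselineLiver,
      relaxivityExtracellular = relaxivityExtracellular,
      relaxivityHepatocellular = relaxivityHepatocellular)
}

#' Model-based input function parameters
#'
#' Parameters of the whole-body gadoxetate model that generates the blood
#' concentration time-course driving the liver model. The default model
#' (`"wholebody-1c"`) infuses the weight-normalised dose at a constant rate
#' over the injection window into a single extracellular distribution volume
#' with first-order elimination.
#'
#' @slot dose injected dose in micromol per kg body weight (protocol: 25)
#' @slot injectionStart bolus start in seconds from the first frame
#' @slot injectionDuration infusion duration in seconds
#' @slot distributionVolume whole-body extracellular volume in mL/kg
#' @slot bodyClearanceRate first-order elimination rate in 1/min
#' @slot modelId registered input-function model identifier
#' @export
setClass("InputFunctionParams", representation(
  dose = "numeric",
  injectionStart = "numeric",
  injectionDuration = "numeric",
  distributionVolume = "numeric",
  bodyClearanceRate = "numeric",
  modelId = "character"
))

setValidity("InputFunctionParams", function(object) {
  msg <- character()
  if (object@dose <= 0) msg <- c(msg, "dose must be positive")
  if (object@injectionDuration <= 0)
    msg <- c(msg, "injectionDuration must be positive")
  if (object@distributionVolume <= 0)
    msg <- c(msg, "distributionVolume must be positive")
  if (object@bodyClearanceRate < 0)
    msg <- c(msg, "bodyClearanceRate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct input-function parameters
#'
#' @param dose micromol gadoxetate per kg body weight.
#' @param injectionStart seconds; by convention the end of the baseline
#'   frames.
#' @param injectionDuration seconds over which the bolus is infused.
#' @param distributionVolume whole-body extracellular volume, mL/kg.
#' @param bodyClearanceRate first-order whole-body elimination rate, 1/min.
#' @param modelId which registered input-function model to use; see
#'   [aifModels()].
#' @return an `InputFunctionParams` object.
#' @export
inputFunctionParams <- function(dose = 25, injectionStart = 50,
                                injectionDuration = 10,
                                distributionVolume = 250,
                                bodyClearanceRate = 0.04,
                                modelId = "wholebody-1c") {
  new("InputFunctionParams", dose = dose, injectionStart = injectionStart,
      injectionDuration = injectionDuration,
      distributionVolume = distributionVolume,
      bodyClearanceRate = bodyClearanceRate, modelId = modelId)
}

#' Kinetic parameters of the two-compartment liver model
#'
#' The fit target: hepatocellular uptake rate Ktrans and biliary efflux rate
#' kbh, both in mL/min/mL of liver tissue, together with the extracellular
#' volume fraction and the arbitrary-unit signal scale.
#'
#' @slot ktrans hepatocellular uptake rate, mL/min/mL (>= 0)
#' @slot kbh biliary efflux rate, mL/min/mL (>= 0)
#' @slot veFraction extracellular volume fraction, in [0, 1]
#' @slot signalScale signal amplitude in arbitrary units (>= 0)
#' @export
setClass("KineticParams", representation(
  ktrans = "numeric",
  kbh = "numeric",
  veFraction = "numeric",
  signalScale = "numeric"
))

setValidity("KineticParams", function(object) {
  msg <- character()
  if (object@ktrans < 0) msg <- c(msg, "ktrans must be >= 0")
  if (object@kbh < 0) msg <- c(msg, "kbh must be >= 0")
  if (object@veFraction < 0 || object@veFraction > 1)
    msg <- c(msg, "veFraction must lie in [0, 1]")
  if (object@signalScale < 0) msg <- c(msg, "signalScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct kinetic parameters
#'
#' @param ktrans,kbh uptake and efflux rates in mL/min/mL.
#' @param veFraction extracellular volume fraction of liver tissue.
#' @param signalScale signal amplitude (arbitrary units).
#' @return a `KineticParams` object.
#' @examples
#' kineticParams(ktrans = 0.90, kbh = 0.19)
#' @export
kineticParams <- function(ktrans = 0.5, kbh = 0.1, veFraction = 0.23,
                          signalScale = 1) {
  new("KineticParams", ktrans = ktrans, kbh = kbh, veFraction = veFraction,
      signalScale = signalScale)
}

#' Container for a cohort of ROI signal-time curves
#'
#' `CurveSet` extends `SummarizedExperiment`: the single assay `"signal"`
#' holds one column per subject-day curve on a common time grid; `rowData`
#' carries the frame times in seconds (`time_s`); `colData` carries the study
#' hierarchy (`subject_id`, `substudy_id`, `centre_id`, `field_strength_T`,
#' `day`, `treatment`). This mirrors the CSV export of ROI curves used by
#' the assay and round-trips losslessly through [writeCurves()] /
#' [readCurves()].
#'
#' @seealso [CurveSet()], [readCurves()], [fitCohort()]
#' @export
#' @import SummarizedExperiment
setClass("CurveSet", contains = "SummarizedExperiment")

.curve_meta_cols <- c("subject_id", "substudy_id", "centre_id",
                      "field_strength_T", "day", "treatment")

setValidity("CurveSet", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is required")
  if (!"time_s" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData column 'time_s' is required")
  else {
    tt <- SummarizedExperiment::rowData(object)$time_s
    if (any(diff(tt) <= 0)) msg <- c(msg, "time_s must be strictly increasing")
  }
  missing <- setdiff(.curve_meta_cols,
                     colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste("colData is missing:", paste(missing, collapse = ", ")))
  if (length(msg) == 0 && ncol(object) > 0) {
    if (any(SummarizedExperiment::assay(object, "signal") < 0, na.rm = TRUE))
      msg <- c(msg, "signal values must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Build a CurveSet from a time grid, a signal matrix and curve metadata
#'
#' @param times numeric vector of frame times in seconds, strictly
#'   increasing.
#' @param signal numeric matrix, `length(times)` rows, one column per curve.
#' @param meta data.frame with one row per curve and columns `subject_id`,
#'   `substudy_id`, `centre_id`, `field_strength_T`, `day`, `treatment`.
#' @return a [CurveSet-class] object.
#' @examples
#' ts <- seq(0, 95, by = 5)
#' sig <- matrix(100, nrow = length(ts), ncol = 1)
#' meta <- data.frame(subject_id = "R1", substudy_id = "S1", centre_id = "D",
#'                    field_strength_T = 4.7, day = 1, treatment = "saline")
#' curveSet(ts, sig, meta)
#' @export
curveSet <- function(times, signal, meta) {
  signal <- as.matrix(signal)
  stopifnot(nrow(signal) == length(times))
  if (nrow(meta) != ncol(signal))
    stop("meta must have one row per signal column")
  ids <- paste(meta$subject_id, meta$day, sep = "_d")
  colnames(signal) <- make.unique(ids)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(signal = signal),
    rowData = S4Vectors::DataFrame(time_s = times),
    colData = S4Vectors::DataFrame(meta, row.names = colnames(signal))
  )
  new("CurveSet", se)
}

#' @describeIn curveSet frame times (seconds) of a CurveSet.
#' @param x a `CurveSet`.
#' @export
curveTimes <- function(x) SummarizedExperiment::rowData(x)$time_s

#' @describeIn curveSet signal matrix (frames x curves, arbitrary units).
#' @export
signalMatrix <- function(x) SummarizedExperiment::assay(x, "signal")

setMethod("show", "CurveSet", function(object) {
  tt <- curveTimes(object)
  cat("CurveSet with", ncol(object), "signal-time curves,",
      nrow(object), "frames\n")
  if (length(tt))
    cat(sprintf("  time grid: %.1f..%.1f s (dt = %.2f s)\n",
                min(tt), max(tt), if (length(tt) > 1) tt[2] - tt[1] else NA))
  cd <- SummarizedExperiment::colData(object)
  if (ncol(object) > 0)
    cat("  substudies:", paste(unique(cd$substudy_id), collapse = ", "),
        "| treatments:", paste(unique(cd$treatment), collapse = ", "), "\n")
})

#' Result of fitting one signal-time curve
#'
#' @slot params fitted [KineticParams-class]
#' @slot residualNorm root-sum-of-squares residual in signal units
#' @slot converged logical convergence flag from the optimizer
#' @slot nIter number of optimizer iterations
#' @slot qcFlags character vector of quality-control flags (empty when the
#'   fit passes QC); any flag marks the curve excluded under the default
#'   policy
#' @slot covarianceDiag named per-parameter variance estimates
#' @export
setClass("FitResult", representation(
  params = "KineticParams",
  residualNorm = "numeric",
  converged = "logical",
  nIter = "integer",
  qcFlags = "character",
  covarianceDiag = "numeric"
))

setMethod("show", "FitResult", function(object) {
  p <- object@params
  cat(sprintf(
    "FitResult: Ktrans = %.4f, kbh = %.4f mL/min/mL (ve = %.2f)\n",
    p@ktrans, p@kbh, p@veFraction))
  cat(sprintf("  residual norm %.4g | converged: %s | iterations: %d\n",
              object@residualNorm, object@converged, object@nIter))
  cat("  QC:", if (length(object@qcFlags)) paste(object@qcFlags,
      collapse = ", ") else "pass", "\n")
})

#' Design of a synthetic multi-centre cohort
#'
#' Encodes the statistical structure the reproducibility analysis assumes: a
#' hierarchy of substudies (centre/field combinations), subjects nested in
#' substudies and two scan days per subject, with multiplicative log-normal
#' variance components expressed as coefficients of variation, a day-2
#' treatment effect for the inhibitor arm, and magnitude noise on the
#' rendered signals.
#'
#' @slot nSubstudies number of substudies
#' @slot subjectsPerArm subjects in each treatment arm of each substudy
#' @slot arms character vector of day-2 treatments present in every
#'   substudy (subset of `c("saline", "rifampicin")`)
#' @slot centres,fieldStrengths per-substudy centre labels and field
#'   strengths (recycled)
#' @slot betweenCentreCv,betweenSubjectCv,betweenDayCv variance components
#'   as coefficients of variation (fractions, not percent)
#' @slot ktransMultiplier,kbhMultiplier multiplicative day-2 inhibitor
#'   effect on each rate (1 = no effect)
#' @slot noiseSdFraction signal noise SD as a fraction of baseline signal
#' @slot noiseModel `"gaussian"` or `"rician"`
#' @slot seed integer seed governing all draws
#' @export
setClass("CohortDesign", representation(
  nSubstudies = "integer",
  subjectsPerArm = "integer",
  arms = "character",
  centres = "character",
  fieldStrengths = "numeric",
  betweenCentreCv = "numeric",
  betweenSubjectCv = "numeric",
  betweenDayCv = "numeric",
  ktransMultiplier = "numeric",
  kbhMultiplier = "numeric",
  noiseSdFraction = "numeric",
  noiseModel = "character",
  seed = "integer"
))

setValidity("CohortDesign", function(object) {
  msg <- character()
  cvs <- c(object@betweenCentreCv, object@betweenSubjectCv,
           object@betweenDayCv)
  if (any(cvs < 0)) msg <- c(msg, "variance-component CVs must be >= 0")
  mult <- c(object@ktransMultiplier, object@kbhMultiplier)
  if (any(mult <= 0) || any(mult > 1))
    msg <- c(msg, "treatment multipliers must lie in (0, 1]")
  if (object@nSubstudies < 1L || object@subjectsPerArm < 1L)
    msg <- c(msg, "need at least one substudy and one subject per arm")
  if (!all(object@arms %in% c("saline", "rifampicin")))
    msg <- c(msg, "arms must be a subset of c('saline', 'rifampicin')")
  if (object@noiseSdFraction < 0)
    msg <- c(msg, "noiseSdFraction must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    msg <- c(msg, "noiseModel must be 'gaussian' or 'rician'")
  if (length(msg)) msg else TRUE
})

#' Construct a synthetic cohort design
#'
#' Defaults describe the validation conditions used throughout the package:
#' three substudies at different centre/field combinations, four subjects
#' per arm, both a saline-saline repeat arm and a saline-rifampicin arm,
#' variance components of 20% (between centre/substudy), 15% (between
#' subject) and 3% (between day), a rifampicin effect multiplying Ktrans by
#' 0.25 and kbh by 0.33 (75% and 67% inhibition), and 3% Gaussian magnitude
#' noise.
#'
#' @param nSubstudies,subjectsPerArm cohort size.
#' @param arms day-2 treatments present in every substudy.
#' @param centres,fieldStrengths per-substudy hardware labels (recycled to
#'   `nSubstudies`).
#' @param betweenCentreCv,betweenSubjectCv,betweenDayCv coefficients of
#'   variation of the hierarchical log-normal effects (fractions).
#' @param ktransMultiplier,kbhMultiplier day-2 inhibitor effect.
#' @param noiseSdFraction magnitude-noise SD as a fraction of baseline
#'   signal.
#' @param noiseModel `"gaussian"` (default, high-SNR volume-coil regime) or
#'   `"rician"`.
#' @param seed integer seed; fixes parameter draws and noise.
#' @return a [CohortDesign-class] object.
#' @examples
#' cohortDesign(nSubstudies = 2, subjectsPerArm = 3, seed = 7)
#' @export
cohortDesign <- function(nSubstudies = 3, subjectsPerArm = 4,
                         arms = c("saline", "rifampicin"),
                         centres = c("D", "E", "G"),
                         fieldStrengths = c(4.7, 7, 7),
                         betweenCentreCv = 0.20, betweenSubjectCv = 0.15,
                         betweenDayCv = 0.03,
                         ktransMultiplier = 0.25, kbhMultiplier = 0.33,
                         noiseSdFraction = 0.03,
                         noiseModel = "gaussian", seed = 1L) {
  n <- as.integer(nSubstudies)
  new("CohortDesign", nSubstudies = n,
      subjectsPerArm = as.integer(subjectsPerArm), arms = arms,
      centres = rep_len(centres, n),
      fieldStrengths = rep_len(fieldStrengths, n),
      betweenCentreCv = betweenCentreCv,
      betweenSubjectCv = betweenSubjectCv, betweenDayCv = betweenDayCv,
      ktransMultiplier = ktransMultiplier, kbhMultiplier = kbhMultiplier,
      noiseSdFraction = noiseSdFraction, noiseModel = noiseModel,
      seed = as.integer(seed))
}

#' Reproducibility report for a cohort of biomarker estimates
#'
#' Collects, per biomarker, the reference value with its confidence
#' interval, reproducibility and repeatability tolerance intervals, absolute
#' and relative detection limits, the inhibitor effect size, the
#' variance-component partition and the between-substudy ANOVA.
#'
#' @slot biomarkers biomarker column names the report covers
#' @slot reference data.frame: biomarker, mean, ci, n_substudies
#' @slot reproducibility data.frame: biomarker, ti_pct
#' @slot repeatability data.frame: biomarker, pct, ci, n_substudies
#' @slot effectSize data.frame: biomarker, pct, ci, n_substudies
#' @slot detectionLimits data.frame: biomarker, absolute_pct, relative_pct
#' @slot varianceComponents data.frame: biomarker, component, pct
#' @slot anova data.frame: biomarker, F, df1, df2, p
#' @export
setClass("ReproReport", representation(
  biomarkers = "character",
  reference = "data.frame",
  reproducibility = "data.frame",
  repeatability = "data.frame",
  effectSize = "data.frame",
  detectionLimits = "data.frame",
  varianceComponents = "data.frame",
  anova = "data.frame"
))

setMethod("show", "ReproReport", function(object) {
  cat("ReproReport over biomarkers:",
      paste(object@biomarkers, collapse = ", "), "\n")
  for (b in object@biomarkers) {
    rf <- object@reference[object@reference$biomarker == b, ]
    rp <- object@reproducibility[object@reproducibility$biomarker == b, ]
    rt <- object@repeatability[object@repeatability$biomarker == b, ]
    es <- object@effectSize[object@effectSize$biomarker == b, ]
    dl <- object@detectionLimits[object@detectionLimits$biomarker == b, ]
    cat(sprintf("  %s: reference %.2f +/- %.2f mL/min/mL (n = %d substudies)\n",
                b, rf$mean, rf$ci, rf$n_substudies))
    cat(sprintf("    reproducibility %.0f%%; repeatability %.0f%%\n",
                rp$ti_pct, rt$pct))
    cat(sprintf("    detection limits: absolute %.0f%%, relative %.0f%%\n",
                dl$absolute_pct, dl$relative_pct))
    if (nrow(es) && is.finite(es$pct))
      cat(sprintf("    inhibitor effect size %.0f +/- %.0f%%\n", es$pct,
                  es$ci))
    vc <- object@varianceComponents
    vc <- vc[vc$biomarker == b, ]
    if (nrow(vc))
      cat("    variance components:",
          paste(sprintf("%s %.1f%%", vc$component, vc$pct), collapse = ", "),
          "\n")
  }
})
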