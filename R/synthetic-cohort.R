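# Synthetic multi-centre cohorts with known ground truth. Variation is
# multiplicative log-normal at each level of the hierarchy (substudy ->
# subject -> day) so rates stay positive at large CVs and the CV
# parameterisation matches percentage-of-mean reporting: sdlog is chosen as
# sqrt(log(1 + cv^2)) and meanlog as -sdlog^2/2, making every factor have
# mean exactly 1 and coefficient of variation exactly cv.

.lnorm_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

# independent substream seeds derived from one master seed (kept < 2^31)
.substream <- function(seed, k) as.integer((seed * 48271 + k) %% 2147483647)

#' Draw ground-truth kinetic parameters for a synthetic cohort
#'
#' Realises the hierarchical variance-component model: each substudy,
#' subject and subject-day receives an independent mean-1 log-normal
#' multiplier per biomarker with the design's coefficient of variation, and
#' day-2 inhibitor arms additionally multiply the rates by the design's
#' treatment multipliers. With all CVs zero every subject-day carries
#' exactly the population means; the draw is fully reproducible from the
#' design seed.
#'
#' @param design a [CohortDesign-class].
#' @param populationMeans named vector `c(Ktrans, kbh)` in mL/min/mL;
#'   defaults are the rat gadoxetate reference values 0.90 and 0.19.
#' @return data.frame with one row per subject-day: metadata labels and the
#'   true `Ktrans_true`, `kbh_true` for that scan.
#' @examples
#' head(drawCohortParams(cohortDesign(seed = 42)))
#' @export
drawCohortParams <- function(design,
                             populationMeans = c(Ktrans = 0.90,
                                                 kbh = 0.19)) {
  stopifnot(is(design, "CohortDesign"))
  set.seed(.substream(design@seed, 1L))
  rows <- list()
  for (s in seq_len(design@nSubstudies)) {
    sub_f <- c(.lnorm_factor(1, design@betweenCentreCv),
               .lnorm_factor(1, design@betweenCentreCv))
    for (arm in design@arms) {
      for (r in seq_len(design@subjectsPerArm)) {
        subj_f <- c(.lnorm_factor(1, design@betweenSubjectCv),
                    .lnorm_factor(1, design@betweenSubjectCv))
        sid <- sprintf("S%02d_%s_R%02d", s, substr(arm, 1, 3), r)
        for (day in 1:2) {
          day_f <- c(.lnorm_factor(1, design@betweenDayCv),
                     .lnorm_factor(1, design@betweenDayCv))
          treat <- if (day == 2) arm else "saline"
          tmult <- if (treat == "rifampicin")
            c(design@ktransMultiplier, design@kbhMultiplier) else c(1, 1)
          kt <- populationMeans[["Ktrans"]] * sub_f[1] * subj_f[1] *
            day_f[1] * tmult[1]
          kb <- populationMeans[["kbh"]] * sub_f[2] * subj_f[2] *
            day_f[2] * tmult[2]
          rows[[length(rows) + 1]] <- data.frame(
            subject_id = sid, substudy_id = sprintf("S%02d", s),
            centre_id = design@centres[s],
            field_strength_T = design@fieldStrengths[s],
            day = day, treatment = treat,
            Ktrans_true = kt, kbh_true = kb,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render signal-time curves for a ground-truth parameter table
#'
#' Pushes every subject-day through the forward model ([liverSignal()])
#' with acquisition, relaxation and input-function constants looked up per
#' centre and field strength from the study configuration, then adds
#' magnitude noise with standard deviation `noiseSdFraction` times the
#' baseline signal — Gaussian by default, Rician
#' (`sqrt((S + n1)^2 + n2^2)`) on request. The output schema is identical
#' to what [readCurves()] accepts, so generated cohorts round-trip through
#' CSV.
#'
#' @param paramTable output of [drawCohortParams()].
#' @param config study configuration list.
#' @param noiseSdFraction noise SD as a fraction of the baseline signal.
#' @param noiseModel `"gaussian"` or `"rician"`.
#' @param seed integer seed for the noise draw.
#' @param veFraction,signalScale forward-model constants shared by all
#'   curves.
#' @return a [CurveSet-class].
#' @export
renderCurves <- function(paramTable, config = defaultStudyConfig(),
                         noiseSdFraction = 0, noiseModel = "gaussian",
                         seed = 1L, veFraction = NULL, signalScale = 100) {
  if (is.null(veFraction))
    veFraction <- config$kinetics$ve_fraction %||% 0.23
  nfr <- config$acquisition$n_frames
  dt <- config$acquisition$frame_interval_s
  tt <- seq(0, by = dt, length.out = nfr)
  set.seed(.substream(seed, 2L))
  sig <- matrix(NA_real_, nrow = nfr, ncol = nrow(paramTable))
  for (j in seq_len(nrow(paramTable))) {
    acq <- lookupAcquisition(config, paramTable$centre_id[j],
                             paramTable$field_strength_T[j])
    relax <- lookupRelaxation(config, paramTable$field_strength_T[j])
    ip <- configInputFunction(config, acq)
    kp <- kineticParams(paramTable$Ktrans_true[j],
                        paramTable$kbh_true[j],
                        veFraction = veFraction,
                        signalScale = signalScale)
    clean <- liverSignal(tt, kp, ip, acq, relax)
    base <- mean(clean[seq_len(acq@nBaselineFrames)])
    sdn <- noiseSdFraction * base
    if (sdn > 0) {
      if (noiseModel == "rician") {
        clean <- sqrt((clean + rnorm(nfr, 0, sdn))^2 +
                        rnorm(nfr, 0, sdn)^2)
      } else {
        clean <- pmax(clean + rnorm(nfr, 0, sdn), 0)
      }
    }
    sig[, j] <- clean
  }
  meta <- paramTable[, c("subject_id", "substudy_id", "centre_id",
                         "field_strength_T", "day", "treatment")]
  curveSet(tt, sig, meta)
}

#' Simulate a full synthetic cohort
#'
#' Convenience wrapper: [drawCohortParams()] followed by [renderCurves()]
#' with the design's noise settings. One master seed drives independent
#' substreams for the parameter draw and the noise, so the same parameter
#' table can be re-rendered at other noise levels.
#'
#' @param design a [CohortDesign-class].
#' @param config study configuration list.
#' @param populationMeans named `c(Ktrans, kbh)` population means.
#' @return list with `curves` (a [CurveSet-class]) and `truth` (the
#'   ground-truth parameter table).
#' @examples
#' \donttest{
#' sim <- simulateCohort(cohortDesign(nSubstudies = 2, subjectsPerArm = 2))
#' }
#' @export
simulateCohort <- function(design, config = defaultStudyConfig(),
                           populationMeans = c(Ktrans = 0.90, kbh = 0.19)) {
  truth <- drawCohortParams(design, populationMeans)
  curves <- renderCurves(truth, config,
                         noiseSdFraction = design@noiseSdFraction,
                         noiseModel = design@noiseModel,
                         seed = design@seed)
  list(curves = curves, truth = truth)
}
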