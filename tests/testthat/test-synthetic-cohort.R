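test_that("zero variance components reproduce the population means exactly", {
  des <- cohortDesign(betweenCentreCv = 0, betweenSubjectCv = 0,
                      betweenDayCv = 0, noiseSdFraction = 0, seed = 4)
  tab <- drawCohortParams(des)
  sal <- tab[tab$treatment == "saline", ]
  expect_true(all(sal$Ktrans_true == 0.90))
  expect_true(all(sal$kbh_true == 0.19))
  rif <- tab[tab$treatment == "rifampicin", ]
  expect_true(all(rif$Ktrans_true == 0.90 * 0.25))
  expect_true(all(rif$kbh_true == 0.19 * 0.33))
})

test_that("zero between-day CV makes saline days identical per subject", {
  des <- cohortDesign(betweenDayCv = 0, seed = 8)
  tab <- drawCohortParams(des)
  sal <- tab[substr(tab$subject_id, 5, 7) == "sal", ]
  for (s in unique(sal$subject_id)) {
    pair <- sal[sal$subject_id == s, ]
    expect_identical(pair$Ktrans_true[1], pair$Ktrans_true[2])
    expect_identical(pair$kbh_true[1], pair$kbh_true[2])
  }
})

test_that("hierarchical draws recover the designed coefficients of
           variation", {
  # moment estimators on the log scale, pooled over replicate cohorts:
  # the model is exactly multiplicative log-normal, so
  #   var(log d2 - log d1) = 2 s_day^2 (within saline subjects),
  #   var(log day-1 | substudy) = s_subj^2 + s_day^2,
  #   var(substudy mean of log day-1) ~= s_sub^2 + (s_subj^2+s_day^2)/n.
  des0 <- cohortDesign(nSubstudies = 3, subjectsPerArm = 8,
                       arms = "saline", betweenCentreCv = 0.20,
                       betweenSubjectCv = 0.15, betweenDayCv = 0.03)
  v_day <- v_subj <- v_sub <- c()
  n <- 8
  for (rep in 1:200) {
    des <- cohortDesign(nSubstudies = 3, subjectsPerArm = n,
                        arms = "saline", betweenCentreCv = 0.20,
                        betweenSubjectCv = 0.15, betweenDayCv = 0.03,
                        seed = 1000 + rep)
    tab <- drawCohortParams(des)
    lk <- log(tab$Ktrans_true)
    d1 <- tab$day == 1
    diffs <- lk[!d1] - lk[d1]
    v_day <- c(v_day, var(diffs) / 2)
    per_sub <- tapply(lk[d1], tab$substudy_id[d1], var)
    v_subj <- c(v_subj, mean(per_sub))
    means <- tapply(lk[d1], tab$substudy_id[d1], mean)
    v_sub <- c(v_sub, var(means))
  }
  to_cv <- function(s2) 100 * sqrt(exp(pmax(s2, 0)) - 1)
  s_day2 <- mean(v_day)
  s_subj2 <- mean(v_subj) - s_day2
  s_sub2 <- mean(v_sub) - (s_subj2 + s_day2) / n
  expect_lt(abs(to_cv(s_day2) - 3), 2)
  expect_lt(abs(to_cv(s_subj2) - 15), 2)
  expect_lt(abs(to_cv(s_sub2) - 20), 2)
})

test_that("noiseless rendering equals the forward model exactly", {
  des <- cohortDesign(nSubstudies = 1, subjectsPerArm = 1,
                      arms = "saline", noiseSdFraction = 0, seed = 3)
  sim <- simulateCohort(des)
  cfg <- defaultStudyConfig()
  tr <- sim$truth[1, ]
  acq <- lookupAcquisition(cfg, tr$centre_id, tr$field_strength_T)
  relax <- lookupRelaxation(cfg, tr$field_strength_T)
  ip <- configInputFunction(cfg, acq)
  expected <- liverSignal(curveTimes(sim$curves),
                          kineticParams(tr$Ktrans_true, tr$kbh_true,
                                        cfg$kinetics$ve_fraction, 100),
                          ip, acq, relax)
  expect_equal(unname(signalMatrix(sim$curves)[, 1]), expected,
               tolerance = 1e-14)
})

test_that("the same seed reproduces the cohort bit for bit", {
  des <- cohortDesign(nSubstudies = 2, subjectsPerArm = 2, seed = 99)
  s1 <- simulateCohort(des); s2 <- simulateCohort(des)
  expect_identical(s1$truth, s2$truth)
  expect_identical(signalMatrix(s1$curves), signalMatrix(s2$curves))
  # different noise levels share the same parameter draw
  des2 <- cohortDesign(nSubstudies = 2, subjectsPerArm = 2, seed = 99,
                       noiseSdFraction = 0)
  expect_identical(simulateCohort(des2)$truth, s1$truth)
})

test_that("rician noise keeps signals non-negative and near-gaussian at
           high SNR", {
  des <- cohortDesign(nSubstudies = 1, subjectsPerArm = 2,
                      arms = "saline", noiseSdFraction = 0.03,
                      noiseModel = "rician", seed = 12)
  sim <- simulateCohort(des)
  sig <- signalMatrix(sim$curves)
  expect_true(all(sig >= 0))
  des0 <- cohortDesign(nSubstudies = 1, subjectsPerArm = 2,
                       arms = "saline", noiseSdFraction = 0, seed = 12)
  clean <- signalMatrix(simulateCohort(des0)$curves)
  expect_lt(max(abs(sig - clean) / clean), 0.25)
})

test_that("a noiseless generated cohort round-trips through CSV and
           fitting to the generating parameters", {
  des <- cohortDesign(nSubstudies = 2, subjectsPerArm = 2,
                      arms = "saline", noiseSdFraction = 0,
                      betweenDayCv = 0.02, seed = 6)
  sim <- simulateCohort(des)
  path <- tempfile(fileext = ".csv")
  writeCurves(sim$curves, path)
  back <- readCurves(path)
  expect_equal(curveTimes(back), curveTimes(sim$curves))
  tab <- fitCohort(back)
  merged <- merge(tab, sim$truth,
                  by = c("subject_id", "day"))
  expect_false(any(merged$excluded))
  expect_equal(merged$Ktrans, merged$Ktrans_true, tolerance = 1e-3)
  expect_equal(merged$kbh, merged$kbh_true, tolerance = 1e-3)
})
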