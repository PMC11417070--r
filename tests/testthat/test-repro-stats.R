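test_that("mean and confidence interval follow the 1.96-sigma definition", {
  expect_equal(meanCI(c(1, 1, 1, 1)), c(mean = 1, ci = 0))
  mc <- meanCI(c(0.8, 1.0))
  expect_equal(unname(mc["mean"]), 0.9)
  expect_equal(unname(mc["ci"]), 1.96 * sd(c(0.8, 1)) / sqrt(2),
               tolerance = 1e-12)
  expect_equal(unname(mc["ci"]), 0.196, tolerance = 1e-3)
  expect_error(meanCI(1), "at least 2")
})

test_that("tolerance interval is 1.96 sd as a percentage of the mean", {
  expect_equal(toleranceIntervalPct(rep(0.5, 6)), 0)
  expect_equal(toleranceIntervalPct(c(0.9, 1.1)), 27.718585822512672,
               tolerance = 1e-10)
  expect_error(toleranceIntervalPct(c(-1, 1)), "zero mean")
})

test_that("repeatability pools each day into its mean before the TI", {
  expect_equal(repeatabilityPct(c(1, 0.9), c(1, 0.9)), 0)
  # frozen from-scratch computation for pairs (1.0, 1.1) and (0.9, 1.0):
  # day means 0.95 / 1.05, overall mean 1.0 -> 1.96 * 0.1/sqrt(2) * 100
  expect_equal(repeatabilityPct(c(1.0, 0.9), c(1.1, 1.0)),
               13.859292911256332, tolerance = 1e-10)
  # differences method re-derived inline: sd(d)/sqrt(2) over the mean
  d1 <- c(1.0, 0.9, 1.05); d2 <- c(1.1, 1.0, 0.98)
  expect_equal(repeatabilityPct(d1, d2, method = "differences"),
               100 * 1.96 * (sd(d2 - d1) / sqrt(2)) / mean(c(d1, d2)),
               tolerance = 1e-12)
  expect_error(repeatabilityPct(numeric(), numeric()), "no valid")
})

test_that("effect size is the percentage drop from the saline mean", {
  expect_equal(effectSizePct(c(1, 1.2), c(1, 1.2)), 0)
  expect_equal(effectSizePct(0.83, 0.20), 100 * (0.83 - 0.20) / 0.83,
               tolerance = 1e-12)  # 75.9
  expect_equal(effectSizePct(0.15, 0.05), 200 / 3, tolerance = 1e-12) # 66.7
  expect_error(effectSizePct(0, 0.1), "zero saline mean")
})

test_that("absolute detection limit closed form agrees with bisection", {
  expect_equal(absoluteDetectionLimit(0, 0), 0)
  # bisection on the overlap condition (1-d)(1+TI) <= 1-CI
  bisect_dl <- function(ti_pct, ci_pct) {
    ti <- ti_pct / 100; ci <- ci_pct / 100
    lo <- 0; hi <- 1
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if ((1 - mid) * (1 + ti) <= 1 - ci) hi <- mid else lo <- mid
    }
    100 * hi
  }
  set.seed(31)
  for (i in 1:1000) {
    ti <- runif(1, 0, 80); ci <- runif(1, 0, 50)
    expect_equal(absoluteDetectionLimit(ti, ci), bisect_dl(ti, ci),
                 tolerance = 0.01)
  }
})

test_that("relative detection limit is exactly sqrt(2) times repeatability", {
  expect_equal(relativeDetectionLimit(0), 0)
  x <- c(25, 8, 3.3, 60)
  expect_equal(relativeDetectionLimit(x), sqrt(2) * x)
  expect_error(relativeDetectionLimit(-1), ">= 0")
})

test_that("variance partition reproduces an independent mixed-ANOVA
           decomposition", {
  tab <- anova_fixture()
  vp <- variancePartition(tab, "Ktrans")
  ss <- attr(vp, "SS")
  # frozen oracle: mixed-design ANOVA (between = substudy, within = day)
  # computed independently, plus direct balanced-design formulas
  expect_equal(unname(ss["between_substudy"]), 0.4350800184,
               tolerance = 1e-6)
  expect_equal(unname(ss["between_subject"]), 0.2855123055,
               tolerance = 1e-6)
  expect_equal(unname(ss["between_day"]), 8.7737e-06, tolerance = 1e-4)
  expect_equal(unname(ss["other"]), 0.004252444 + 0.0024975923,
               tolerance = 1e-6)
  expect_equal(as.numeric(vp), c(59.8170537, 39.2537101, 0.00120626,
                                 0.92802995), tolerance = 1e-5)
  expect_equal(sum(vp), 100, tolerance = 1e-8)
  expect_true(all(vp >= 0))
})

test_that("identical days give a vanishing between-day component", {
  tab <- anova_fixture()
  d1 <- tab[tab$day == 1, ]
  d2 <- d1; d2$day <- 2
  same <- rbind(d1, d2)
  vp <- variancePartition(same, "Ktrans")
  expect_lt(unname(vp["between_day"]), 1e-10)
  expect_error(variancePartition(d1, "Ktrans"), "repeat data")
})

test_that("group comparison matches a frozen one-way ANOVA and flags
           degenerate input", {
  tab <- anova_fixture()
  gc <- groupComparison(tab, "substudy_id", "Ktrans", day = 1)
  expect_equal(gc$F, 8.50800600245017, tolerance = 1e-8)
  expect_equal(gc$p, 0.00842379972621391, tolerance = 1e-8)
  expect_false(gc$degenerate)
  pw <- attr(gc, "pairwise")
  expect_true(!is.null(pw) && all(pw > 0 & pw < 1, na.rm = TRUE))
  flat <- tab; flat$Ktrans <- 1
  expect_true(groupComparison(flat, "substudy_id", "Ktrans")$degenerate)
  expect_error(groupComparison(tab[1:2, ], "substudy_id", "Ktrans"),
               ">= 2 groups")
})

test_that("report assembles every statistic and respects exclusions", {
  tab <- anova_fixture()
  # add a rifampicin arm to substudy s1 with a 75%/67% drop
  rif_base <- cohort_row("s1", paste0("s1_t", 1:3), 1, "saline",
                         c(0.9, 0.95, 0.85), c(0.2, 0.19, 0.21))
  rif_fup <- cohort_row("s1", paste0("s1_t", 1:3), 2, "rifampicin",
                        c(0.9, 0.95, 0.85) * 0.25,
                        c(0.2, 0.19, 0.21) * 0.33)
  full <- rbind(tab, rif_base, rif_fup)
  rep <- reproReport(full)
  expect_s4_class(rep, "ReproReport")
  ref <- rep@reference[rep@reference$biomarker == "Ktrans", ]
  means <- tapply(full$Ktrans[full$day == 1 & full$treatment == "saline"],
                  full$substudy_id[full$day == 1 &
                                     full$treatment == "saline"], mean)
  expect_equal(ref$mean, mean(means), tolerance = 1e-12)
  es <- rep@effectSize[rep@effectSize$biomarker == "Ktrans", ]
  expect_equal(es$pct, 75, tolerance = 1e-6)
  es_k <- rep@effectSize[rep@effectSize$biomarker == "kbh", ]
  expect_equal(es_k$pct, 67, tolerance = 1e-6)
  dl <- rep@detectionLimits[rep@detectionLimits$biomarker == "Ktrans", ]
  expect_equal(dl$absolute_pct,
               absoluteDetectionLimit(
                 toleranceIntervalPct(means),
                 100 * 1.96 * sd(means) / sqrt(length(means)) / mean(means)),
               tolerance = 1e-10)
  vc <- rep@varianceComponents
  expect_equal(sum(vc$pct[vc$biomarker == "Ktrans"]), 100,
               tolerance = 1e-6)
  # an excluded row must not move any statistic
  spiked <- rbind(full, cohort_row("s1", "weird", 1, "saline", 50, 50))
  spiked$excluded[nrow(spiked)] <- TRUE
  rep2 <- reproReport(spiked)
  expect_equal(rep2@reference$mean, rep@reference$mean, tolerance = 1e-12)
})
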