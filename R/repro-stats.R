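# Reproducibility framework: reference values, tolerance intervals,
# detection limits, effect sizes and variance partition. Normal-theory 1.96
# multipliers are used exactly as defined (no small-sample t correction):
# the definitions fix the constant.

#' Mean with 95% confidence interval
#'
#' The confidence interval half-width is defined as 1.96 times the standard
#' error of the mean.
#'
#' @param values numeric vector, `n >= 2`.
#' @return named vector `c(mean, ci)`.
#' @examples
#' meanCI(c(0.8, 1.0))  # mean 0.9, ci 1.96 * sd / sqrt(2)
#' @export
meanCI <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("meanCI needs at least 2 values")
  c(mean = mean(values), ci = 1.96 * sd(values) / sqrt(n))
}

#' 95% tolerance interval as a percentage of the mean
#'
#' Defined as 1.96 times the standard deviation, expressed as a percentage
#' of the mean: the spread a single new measurement is expected to fall
#' within. Computed over substudy means, this is the between-substudy
#' reproducibility of the assay.
#'
#' @param values numeric vector, `n >= 2`, non-zero mean.
#' @return percentage.
#' @examples
#' toleranceIntervalPct(c(0.9, 1.1))  # 27.7%
#' @export
toleranceIntervalPct <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("tolerance interval undefined for zero mean")
  100 * 1.96 * sd(values) / m
}

#' Within-subject repeatability as a percentage
#'
#' Repeatability of a single measurement from saline-saline repeat data of
#' one substudy. Each scan day is first pooled into its substudy mean (a
#' substudy returns one mean value per biomarker per day); the default
#' (`method = "pooled"`) then takes the tolerance interval of the baseline
#' and follow-up day means as a percentage of the overall mean, so
#' identical day-1 and day-2 data give exactly 0%.
#' `method = "differences"` instead estimates the within-subject SD from
#' paired day differences (`sd(d) / sqrt(2)`) and expresses `1.96 * sd_w`
#' as a percentage of the overall mean. The cohort-level repeatability is
#' the mean over substudies with its confidence interval.
#'
#' @param day1,day2 paired same-subject saline values for one substudy.
#' @param method `"pooled"` (default) or `"differences"`.
#' @return percentage for the substudy.
#' @export
repeatabilityPct <- function(day1, day2, method = c("pooled",
                                                    "differences")) {
  method <- match.arg(method)
  ok <- is.finite(day1) & is.finite(day2)
  day1 <- day1[ok]; day2 <- day2[ok]
  if (length(day1) == 0) stop("no valid saline-saline pairs")
  m <- mean(c(day1, day2))
  if (m == 0) stop("repeatability undefined for zero mean")
  if (method == "pooled") {
    100 * 1.96 * sd(c(mean(day1), mean(day2))) / m
  } else {
    if (length(day1) < 2) stop("need >= 2 pairs for the differences method")
    sdw <- sd(day2 - day1) / sqrt(2)
    100 * 1.96 * sdw / m
  }
}

#' Inhibitor effect size as a percentage of the saline value
#'
#' The difference between the saline value and the inhibited value,
#' expressed as a percentage of the saline value:
#' `100 * (mean(saline) - mean(treated)) / mean(saline)`.
#'
#' @param saline,treated biomarker values under saline and under the
#'   inhibitor (typically day-1 and day-2 means of the treated arm of one
#'   substudy).
#' @return percentage (positive for inhibition).
#' @examples
#' effectSizePct(0.83, 0.20)  # 75.9%
#' @export
effectSizePct <- function(saline, treated) {
  saline <- saline[is.finite(saline)]; treated <- treated[is.finite(treated)]
  if (!length(saline) || !length(treated)) stop("both groups must be non-empty")
  ms <- mean(saline)
  if (ms == 0) stop("effect size undefined for zero saline mean")
  100 * (ms - mean(treated)) / ms
}

#' Absolute detection limit of an inhibition effect
#'
#' Smallest inhibition `d` (as a fraction of the benchmark) whose 95%
#' tolerance interval — with relative width set by the saline
#' reproducibility — no longer overlaps the confidence interval of the
#' saline benchmark. Solving `(1 - d)(1 + TI) = 1 - CI` gives the closed
#' form `d = 1 - (1 - CI) / (1 + TI)` with TI and CI as fractions.
#'
#' @param reproducibilityPct between-substudy reproducibility (tolerance
#'   interval) as a percentage of the mean, in `[0, 100)`.
#' @param benchmarkCiRelPct relative confidence interval of the benchmark,
#'   percent of the benchmark mean, in `[0, 100)`.
#' @return smallest detectable inhibition, percent.
#' @examples
#' absoluteDetectionLimit(31, 100 * 0.08 / 0.90)  # ~30% for Ktrans
#' @export
absoluteDetectionLimit <- function(reproducibilityPct, benchmarkCiRelPct) {
  ti <- reproducibilityPct / 100
  ci <- benchmarkCiRelPct / 100
  if (ti <= -1) stop("tolerance interval must exceed -100%")
  if (ti < 0 || ci < 0 || ci >= 1)
    stop("percent inputs must lie in [0, 100)")
  100 * (1 - (1 - ci) / (1 + ti))
}

#' Relative detection limit of a between-day change
#'
#' Smallest between-day change whose confidence interval does not contain
#' zero, with the error on the difference of two paired measurements taken
#' as the saline repeatability inflated by sqrt(2) — the repeatability
#' coefficient (RC).
#'
#' @param repeatabilityPct within-subject repeatability, percent, `>= 0`.
#' @return `sqrt(2) * repeatabilityPct`, percent.
#' @examples
#' relativeDetectionLimit(25)  # ~35% for Ktrans
#' relativeDetectionLimit(8)   # ~11% for kbh
#' @export
relativeDetectionLimit <- function(repeatabilityPct) {
  if (any(repeatabilityPct < 0)) stop("repeatability must be >= 0")
  sqrt(2) * repeatabilityPct
}

.check_cohort_cols <- function(table, biomarker) {
  need <- c("substudy_id", "subject_id", "day", "treatment", biomarker)
  miss <- setdiff(need, colnames(table))
  if (length(miss))
    stop("cohort table is missing columns: ", paste(miss, collapse = ", "))
  if ("excluded" %in% colnames(table)) table <- table[!table$excluded, ]
  table
}

#' Partition variance into between-substudy, between-subject and
#' between-day components
#'
#' Two-way mixed-effects ANOVA on saline-saline repeat data with day as the
#' within-subject factor and substudy as the between factor (subjects
#' nested in substudies). The sums of squares are converted to percentages
#' of the total: `between_substudy`, `between_subject` (subjects within
#' substudy), `between_day`, and `other` (day-by-substudy interaction plus
#' residual), which sum to 100.
#'
#' @param table cohort table with columns `substudy_id`, `subject_id`,
#'   `day`, `treatment`, the biomarker column, and optionally `excluded`.
#'   Only saline rows of subjects measured on both days enter the ANOVA.
#' @param biomarker name of the biomarker column (e.g. `"Ktrans"`).
#' @return named numeric vector of the four percentages plus attribute
#'   `"SS"` with the raw sums of squares.
#' @export
variancePartition <- function(table, biomarker = "Ktrans") {
  table <- .check_cohort_cols(table, biomarker)
  tab <- table[table$treatment == "saline", ]
  cnt <- base::table(tab$subject_id)
  keep <- names(cnt)[cnt == 2]
  tab <- tab[tab$subject_id %in% keep, ]
  if (nrow(tab) < 8 || length(unique(tab$substudy_id)) < 2)
    stop("variance partition needs >= 2 substudies of saline-saline ",
         "repeat data (both days per subject)")
  df <- data.frame(
    y = tab[[biomarker]],
    substudy = factor(tab$substudy_id),
    subject = factor(tab$subject_id),
    day = factor(tab$day))
  fit <- aov(y ~ substudy * day + Error(subject), data = df)
  sm <- summary(fit)
  ss_between <- sm[["Error: subject"]][[1]]
  ss_within <- sm[["Error: Within"]][[1]]
  pick <- function(tbl, term) {
    i <- match(term, trimws(rownames(tbl)))
    if (is.na(i)) 0 else tbl[i, "Sum Sq"]
  }
  ss <- c(
    between_substudy = pick(ss_between, "substudy"),
    between_subject = pick(ss_between, "Residuals"),
    between_day = pick(ss_within, "day"),
    other = pick(ss_within, "substudy:day") + pick(ss_within, "Residuals"))
  if (any(!is.finite(ss)))
    stop("design too unbalanced for the variance partition")
  pct <- 100 * ss / sum(ss)
  attr(pct, "SS") <- ss
  pct
}

#' One-way ANOVA across strata with pairwise t-tests
#'
#' Tests for systematic differences of a biomarker between levels of a
#' stratification label (substudy, centre, field strength, time period)
#' using a standard one-way ANOVA, with unpaired pairwise t-tests (no
#' pooled SD, no multiple-comparison adjustment — the analyses are
#' exploratory by design). Degenerate inputs (all groups constant and
#' equal) are reported with `degenerate = TRUE` and an undefined F.
#'
#' @param table cohort table (see [variancePartition()]).
#' @param stratifyBy column to group by, default `"substudy_id"`.
#' @param biomarker biomarker column name.
#' @param day which scan day to test (default 1, the common baseline).
#' @param paired use paired t-tests (same subjects across strata); only the
#'   pairwise tests are affected.
#' @return a one-row data.frame with `F`, `df1`, `df2`, `p`, `degenerate`;
#'   attribute `"pairwise"` holds the pairwise t-test p-value matrix.
#' @export
groupComparison <- function(table, stratifyBy = "substudy_id",
                            biomarker = "Ktrans", day = 1,
                            paired = FALSE) {
  table <- .check_cohort_cols(table, biomarker)
  tab <- table[table$day == day & table$treatment == "saline", ]
  g <- factor(tab[[stratifyBy]])
  y <- tab[[biomarker]]
  sizes <- base::table(g)
  if (length(sizes) < 2 || any(sizes < 2))
    stop("need >= 2 groups with >= 2 values each")
  if (all(tapply(y, g, sd) == 0) &&
      length(unique(tapply(y, g, mean))) == 1) {
    out <- data.frame(F = NA_real_, df1 = length(sizes) - 1L,
                      df2 = length(y) - length(sizes), p = NA_real_,
                      degenerate = TRUE)
    return(out)
  }
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  out <- data.frame(F = unname(ow$statistic),
                    df1 = unname(ow$parameter[1]),
                    df2 = unname(ow$parameter[2]),
                    p = ow$p.value, degenerate = FALSE)
  pw <- try(pairwise.t.test(y, g, p.adjust.method = "none",
                            pool.sd = FALSE, paired = paired)$p.value,
            silent = TRUE)
  if (!inherits(pw, "try-error")) attr(out, "pairwise") <- pw
  out
}

# per-substudy day-1 saline means (the unit over which reference values and
# reproducibility are defined: each substudy contributes one mean)
.substudy_baseline_means <- function(table, biomarker) {
  tab <- table[table$day == 1 & table$treatment == "saline", ]
  out <- tapply(tab[[biomarker]], tab$substudy_id, mean)
  out[is.finite(out)]
}

#' Build the full reproducibility report for a cohort table
#'
#' Runs every statistic of the reproducibility framework on a cohort table
#' of per-subject-day biomarker estimates: substudy baseline means,
#' reference value with confidence interval, between-substudy
#' reproducibility (tolerance interval over substudy means), within-subject
#' repeatability from saline-saline substudies (mean over substudies with
#' CI), inhibitor effect size from saline-inhibitor substudies (mean over
#' substudies with CI), absolute and relative detection limits, the
#' mixed-ANOVA variance partition, and the between-substudy one-way ANOVA.
#' Substudies with fewer than two valid repeat subjects are dropped from
#' the repeatability and effect-size aggregation; excluded rows are ignored
#' throughout.
#'
#' @param table cohort table as returned by [fitCohort()].
#' @param biomarkers biomarker columns to report on.
#' @param repeatabilityMethod passed to [repeatabilityPct()].
#' @return a [ReproReport-class] object.
#' @export
reproReport <- function(table, biomarkers = c("Ktrans", "kbh"),
                        repeatabilityMethod = "pooled") {
  ref <- rep_df <- es <- dl <- vc <- av <- repro <- NULL
  for (b in biomarkers) {
    tab <- .check_cohort_cols(table, b)
    means <- .substudy_baseline_means(tab, b)
    if (length(means) < 2)
      stop("need >= 2 substudies with day-1 saline data for ", b)
    mc <- meanCI(means)
    ti <- toleranceIntervalPct(means)
    ref <- rbind(ref, data.frame(
      biomarker = b, mean = unname(mc["mean"]), ci = unname(mc["ci"]),
      n_substudies = length(means)))
    repro <- rbind(repro, data.frame(biomarker = b, ti_pct = ti))

    # repeatability: saline on both days, >= 2 complete subjects
    rep_vals <- c()
    for (s in unique(tab$substudy_id)) {
      sub <- tab[tab$substudy_id == s & tab$treatment == "saline", ]
      wide <- .pair_days(sub, b)
      if (nrow(wide) >= 2)
        rep_vals <- c(rep_vals, repeatabilityPct(
          wide$day1, wide$day2, method = repeatabilityMethod))
    }
    rep_row <- if (length(rep_vals) >= 2) {
      rc <- meanCI(rep_vals)
      data.frame(biomarker = b, pct = unname(rc["mean"]),
                 ci = unname(rc["ci"]), n_substudies = length(rep_vals))
    } else if (length(rep_vals) == 1) {
      data.frame(biomarker = b, pct = rep_vals, ci = NA_real_,
                 n_substudies = 1L)
    } else {
      data.frame(biomarker = b, pct = NA_real_, ci = NA_real_,
                 n_substudies = 0L)
    }
    rep_df <- rbind(rep_df, rep_row)

    # effect size: same-subject saline day 1 vs inhibitor day 2
    es_vals <- c()
    for (s in unique(tab$substudy_id)) {
      sub <- tab[tab$substudy_id == s, ]
      rif <- sub[sub$treatment == "rifampicin" & sub$day == 2, ]
      if (nrow(rif) < 2) next
      base <- sub[sub$day == 1 & sub$treatment == "saline" &
                    sub$subject_id %in% rif$subject_id, ]
      if (nrow(base) < 2) next
      es_vals <- c(es_vals, effectSizePct(base[[b]], rif[[b]]))
    }
    es_row <- if (length(es_vals) >= 2) {
      ec <- meanCI(es_vals)
      data.frame(biomarker = b, pct = unname(ec["mean"]),
                 ci = unname(ec["ci"]), n_substudies = length(es_vals))
    } else if (length(es_vals) == 1) {
      data.frame(biomarker = b, pct = es_vals, ci = NA_real_,
                 n_substudies = 1L)
    } else {
      data.frame(biomarker = b, pct = NA_real_, ci = NA_real_,
                 n_substudies = 0L)
    }
    es <- rbind(es, es_row)

    dl <- rbind(dl, data.frame(
      biomarker = b,
      absolute_pct = unname(absoluteDetectionLimit(
        ti, unname(100 * mc["ci"] / mc["mean"]))),
      relative_pct = if (is.finite(rep_row$pct))
        relativeDetectionLimit(rep_row$pct) else NA_real_))

    vp <- try(variancePartition(tab, b), silent = TRUE)
    if (!inherits(vp, "try-error"))
      vc <- rbind(vc, data.frame(biomarker = b, component = names(vp),
                                 pct = as.numeric(vp)))
    gc <- try(groupComparison(tab, "substudy_id", b), silent = TRUE)
    if (!inherits(gc, "try-error"))
      av <- rbind(av, cbind(biomarker = b, gc))
  }
  rownames(dl) <- NULL
  new("ReproReport", biomarkers = biomarkers, reference = ref,
      reproducibility = repro, repeatability = rep_df, effectSize = es,
      detectionLimits = dl,
      varianceComponents = if (is.null(vc)) data.frame() else vc,
      anova = if (is.null(av)) data.frame() else av)
}

# wide day1/day2 table for subjects measured on both days
.pair_days <- function(sub, biomarker) {
  d1 <- sub[sub$day == 1, c("subject_id", biomarker)]
  d2 <- sub[sub$day == 2, c("subject_id", biomarker)]
  wide <- merge(d1, d2, by = "subject_id", suffixes = c("_1", "_2"))
  data.frame(subject_id = wide$subject_id,
             day1 = wide[[paste0(biomarker, "_1")]],
             day2 = wide[[paste0(biomarker, "_2")]])
}
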