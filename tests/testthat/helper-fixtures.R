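# Shared fixtures: default model constants, a clean forward curve, and a
# frozen balanced saline-saline dataset for the variance partition (the
# expected sums of squares were computed independently with a mixed-design
# ANOVA implementation and direct balanced-design formulas).

default_acq <- function(...) acquisitionParams(...)
default_relax <- function(...) relaxationParams(...)
default_ip <- function(...) inputFunctionParams(...)

time_grid <- function(n = 360, dt = 5) seq(0, by = dt, length.out = n)

clean_curve <- function(ktrans, kbh, scale = 100, ve = 0.23,
                        t = time_grid(), acq = default_acq(),
                        relax = default_relax(), ip = default_ip()) {
  liverSignal(t, kineticParams(ktrans, kbh, ve, scale), ip, acq, relax)
}

# long-format cohort table straight from biomarker values (no fitting)
cohort_row <- function(substudy, subject, day, treatment, kt, kb) {
  data.frame(subject_id = subject, substudy_id = substudy,
             centre_id = "D", field_strength_T = 4.7, day = day,
             treatment = treatment, Ktrans = kt, kbh = kb,
             excluded = FALSE, stringsAsFactors = FALSE)
}

# 3 substudies x 4 subjects x 2 days, saline-saline; frozen values
anova_fixture <- function() {
  y <- c(0.903705, 0.9708, 0.958566, 0.98377, 0.905893, 0.916809,
         0.820254, 0.816927,
         1.220955, 1.189157, 1.030965, 0.977644, 1.315754, 1.308672,
         1.095709, 1.036986,
         0.716272, 0.742066, 0.831907, 0.832509, 1.050882, 1.046443,
         0.702727, 0.717295)
  grid <- expand.grid(day = 1:2, subject = 1:4, substudy = c("s1", "s2", "s3"))
  data.frame(
    subject_id = paste0(grid$substudy, "_r", grid$subject),
    substudy_id = as.character(grid$substudy),
    centre_id = "D", field_strength_T = 4.7,
    day = grid$day, treatment = "saline",
    Ktrans = y, kbh = y, excluded = FALSE,
    stringsAsFactors = FALSE)
}
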