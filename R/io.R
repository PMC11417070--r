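# CSV readers/writers. The native curve schema is long format with units in
# the column names: time_s, signal, subject_id, substudy_id, centre_id,
# field_strength_T, day, treatment; one file per cohort. A column mapping
# allows reading foreign CSV dialects of the same content.

.curve_cols <- c("time_s", "signal", .curve_meta_cols)

#' Read signal-time curves from CSV
#'
#' Reads a long-format cohort CSV into a [CurveSet-class]. Required columns
#' are `time_s`, `signal` and the metadata labels `subject_id`,
#' `substudy_id`, `centre_id`, `field_strength_T`, `day`, `treatment`;
#' `mapping` renames foreign column names onto this schema (e.g.
#' `c(time_s = "Time", signal = "ROI_mean")`). Each subject-day must sit on
#' the same strictly increasing time grid; violations are reported with the
#' offending curve and line numbers.
#'
#' @param path CSV file path.
#' @param mapping named character vector: native column name -> column name
#'   in the file.
#' @return a [CurveSet-class].
#' @seealso [writeCurves()] for the inverse; the pair round-trips
#'   losslessly.
#' @export
readCurves <- function(path, mapping = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      if (!mapping[[nm]] %in% colnames(df))
        stop("mapped column '", mapping[[nm]], "' not in file")
      colnames(df)[colnames(df) == mapping[[nm]]] <- nm
    }
  }
  miss <- setdiff(.curve_cols, colnames(df))
  if (length(miss))
    stop("curve CSV is missing required columns: ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$time_s) | !is.finite(df$signal))
  if (length(bad))
    stop("non-numeric time/signal values at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  id <- paste(df$subject_id, df$day, sep = "_d")
  split_rows <- split(seq_len(nrow(df)), id)
  tt <- df$time_s[split_rows[[1]]]
  if (is.unsorted(tt, strictly = TRUE)) {
    off <- which(diff(tt) <= 0)[1]
    stop("times not strictly increasing for curve ", names(split_rows)[1],
         " (near line ", split_rows[[1]][off + 1] + 1L, ")")
  }
  sig <- matrix(NA_real_, nrow = length(tt), ncol = length(split_rows))
  meta <- NULL
  for (j in seq_along(split_rows)) {
    idx <- split_rows[[j]]
    tj <- df$time_s[idx]
    if (length(tj) != length(tt) || any(tj != tt)) {
      if (is.unsorted(tj, strictly = TRUE))
        stop("times not strictly increasing for curve ",
             names(split_rows)[j], " (near line ",
             idx[which(diff(tj) <= 0)[1] + 1] + 1L, ")")
      stop("curve ", names(split_rows)[j],
           " is not on the common time grid")
    }
    sig[, j] <- df$signal[idx]
    meta <- rbind(meta, df[idx[1], .curve_meta_cols])
  }
  curveSet(tt, sig, meta)
}

#' Write a CurveSet to CSV
#'
#' @param curves a [CurveSet-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCurves <- function(curves, path) {
  stopifnot(is(curves, "CurveSet"))
  cd <- as.data.frame(SummarizedExperiment::colData(curves))
  tt <- curveTimes(curves)
  sig <- signalMatrix(curves)
  long <- do.call(rbind, lapply(seq_len(ncol(curves)), function(j) {
    data.frame(time_s = tt, signal = sig[, j],
               cd[j, .curve_meta_cols, drop = FALSE],
               row.names = NULL)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read/write a cohort table of biomarker estimates
#'
#' Thin CSV wrappers around the cohort table produced by [fitCohort()];
#' rates are in mL/min/mL as the column documentation states.
#'
#' @param table cohort table data.frame.
#' @param path CSV path.
#' @return `readCohortTable()` returns the data.frame; the writer returns
#'   `path` invisibly.
#' @export
writeCohortTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortTable
#' @export
readCohortTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.csv(path, stringsAsFactors = FALSE)
}

.report_as_list <- function(report) {
  list(
    biomarkers = report@biomarkers,
    reference = report@reference,
    reproducibility = report@reproducibility,
    repeatability = report@repeatability,
    effect_size = report@effectSize,
    detection_limits = report@detectionLimits,
    variance_components = report@varianceComponents,
    anova = report@anova)
}

#' Write a reproducibility report to disk
#'
#' Writes three views of a [ReproReport-class]: `report.json` (full
#' precision), `report.csv` (flat metric table with display rounding:
#' percentages to one decimal, detection limits also reported rounded to
#' integer percent) and `report.txt` (human-readable summary in the style
#' of a results section).
#'
#' @param report a [ReproReport-class].
#' @param dir output directory, created if needed.
#' @return named character vector of the files written, invisibly.
#' @export
writeReport <- function(report, dir) {
  stopifnot(is(report, "ReproReport"))
  if (nrow(report@reference) == 0)
    stop("refusing to write an empty report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(.report_as_list(report), json_path,
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  flat <- NULL
  for (b in report@biomarkers) {
    g <- function(df, col) df[df$biomarker == b, col]
    flat <- rbind(flat, data.frame(
      biomarker = b,
      reference_mean = g(report@reference, "mean"),
      reference_ci = g(report@reference, "ci"),
      reproducibility_pct = round(g(report@reproducibility, "ti_pct"), 1),
      repeatability_pct = round(g(report@repeatability, "pct"), 1),
      effect_size_pct = round(g(report@effectSize, "pct"), 1),
      effect_size_ci = round(g(report@effectSize, "ci"), 1),
      abs_detection_limit_pct = round(g(report@detectionLimits,
                                        "absolute_pct")),
      rel_detection_limit_pct = round(g(report@detectionLimits,
                                        "relative_pct"))))
  }
  csv_path <- file.path(dir, "report.csv")
  write.csv(flat, csv_path, row.names = FALSE)

  txt_path <- file.path(dir, "report.txt")
  con <- file(txt_path, "w")
  on.exit(close(con))
  sink(con); show(report); sink()
  invisible(c(json = json_path, csv = csv_path, txt = txt_path))
}
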