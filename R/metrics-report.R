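# Evaluation arithmetic: per-patient descriptive statistics for images,
# seconds and bytes per strategy, and the whole-hospital extrapolation
# from mean per-patient extraction time.

#' Descriptive statistics of a per-patient metric
#'
#' Mean, median, quartiles, minimum and maximum. Quartiles use linear
#' interpolation between order statistics (the common statistical-
#' package default, `quantile` type 7). Robust to the strong right
#' skew of per-patient imaging counts.
#'
#' @param values Non-empty numeric vector.
#' @return Named list: `mean`, `median`, `q1`, `q3`, `min`, `max`.
#' @export
cohort_stats <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || anyNA(values))
    stop("cohort_stats requires a non-empty numeric vector without NA",
         call. = FALSE)
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  list(mean = mean(values), median = q[2], q1 = q[1], q3 = q[3],
       min = min(values), max = max(values))
}

#' Extrapolate whole-hospital extraction time
#'
#' Days needed to extract `n_patients` patients at a given mean
#' per-patient extraction time:
#' `days = mean_seconds_per_patient * n_patients / 86400`,
#' rounded half-up to an integer.
#'
#' @param mean_seconds_per_patient Positive mean seconds per patient.
#' @param n_patients Positive patient count.
#' @return Integer number of days.
#' @export
extrapolate_days <- function(mean_seconds_per_patient, n_patients) {
  if (!is.numeric(mean_seconds_per_patient) || length(mean_seconds_per_patient) != 1L ||
      is.na(mean_seconds_per_patient) || mean_seconds_per_patient <= 0)
    stop("mean_seconds_per_patient must be a positive number", call. = FALSE)
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      is.na(n_patients) || n_patients <= 0)
    stop("n_patients must be a positive number", call. = FALSE)
  as.integer(floor(mean_seconds_per_patient * n_patients / 86400 + 0.5))
}

#' Reference per-patient extraction figures from a production PACS
#'
#' Published per-patient means observed when bulk-extracting a
#' 1000-patient test cohort (988 with imaging detected) from a
#' university hospital's production PACS with the three strategies.
#' Useful as inputs to [extrapolate_days()] and as an order-of-
#' magnitude yardstick for synthetic runs.
#'
#' @format List with `n_cohort`, `n_detected` and per-strategy entries
#'   (`basic_first`, `basic_all`, `extended_first`), each holding
#'   `mean_images`, `mean_seconds` and `mean_kib` per patient.
#' @export
pacs_reference_stats <- list(
  n_cohort = 1000L,
  n_detected = 988L,
  basic_first = list(mean_images = 26.5, mean_seconds = 2.76, mean_kib = 417.5),
  basic_all = list(mean_images = 1004, mean_seconds = 3.92, mean_kib = 417.1),
  extended_first = list(mean_images = 26.5, mean_seconds = 34.10,
                        mean_kib = 123120.8)
)

.metric_block <- function(per_patient) {
  det <- per_patient[per_patient$detected, ]
  list(images = cohort_stats(det$n_images),
       seconds = cohort_stats(det$seconds),
       bytes = cohort_stats(det$bytes))
}

#' Render a strategy comparison report
#'
#' One block per extraction strategy with the three per-patient metric
#' families (number of images, seconds, bytes), each summarized as
#' mean, median, quartiles, minimum and maximum over detected patients,
#' plus an optional whole-hospital extrapolation from each strategy's
#' mean per-patient time. Reports over different patient sets are
#' flagged with a warning field.
#'
#' @param reports List of `extraction_report`s (at least one).
#' @param extrapolate_to Optional patient count for the extrapolation
#'   section.
#' @return Object of class `strategy_report`: list with `strategies`
#'   (named blocks), `extrapolation` and `warning`; `format()` renders
#'   an aligned text table, [report_json()] a JSON document.
#' @export
render_report <- function(reports, extrapolate_to = NULL) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  if (inherits(reports, "extraction_report")) reports <- list(reports)
  stopifnot(all(vapply(reports, inherits, logical(1), "extraction_report")))
  cohorts <- lapply(reports, function(r) sort(r$per_patient$pseudonym))
  warn <- if (length(unique(vapply(cohorts, paste, character(1),
                                   collapse = "|"))) > 1L)
    "reports cover different patient sets" else NULL
  blocks <- lapply(reports, function(r) {
    c(list(strategy = r$strategy,
           patients = r$totals$patients,
           patients_detected = r$totals$patients_detected,
           total_images = r$totals$images,
           quarantined = r$import$quarantined),
      .metric_block(r$per_patient))
  })
  names(blocks) <- vapply(reports, `[[`, character(1), "strategy")
  extrap <- NULL
  if (!is.null(extrapolate_to)) {
    extrap <- lapply(blocks, function(b)
      list(n_patients = extrapolate_to,
           days = extrapolate_days(max(b$seconds$mean, 1e-9), extrapolate_to)))
  }
  structure(list(strategies = blocks, extrapolation = extrap, warning = warn),
            class = "strategy_report")
}

#' JSON form of a strategy report
#'
#' Numeric fields round-trip exactly through [jsonlite::fromJSON()].
#'
#' @param report A `strategy_report`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
report_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  if (!is.null(path)) writeLines(js, path)
  js
}

#' @export
format.strategy_report <- function(x, ...) {
  fmt_stats <- function(s) sprintf(
    "mean %10.2f  median %10.2f  (q1 %10.2f - q3 %10.2f)  min %10.2f  max %12.2f",
    s$mean, s$median, s$q1, s$q3, s$min, s$max)
  lines <- character()
  for (b in x$strategies) {
    lines <- c(lines,
      sprintf("strategy %-16s patients %d detected %d images %d quarantined %d",
              b$strategy, b$patients, b$patients_detected, b$total_images,
              b$quarantined),
      paste0("  images/patient : ", fmt_stats(b$images)),
      paste0("  seconds/patient: ", fmt_stats(b$seconds)),
      paste0("  bytes/patient  : ", fmt_stats(b$bytes)))
  }
  if (!is.null(x$extrapolation)) {
    lines <- c(lines, "extrapolation:")
    for (nm in names(x$extrapolation))
      lines <- c(lines, sprintf("  %-16s %d patients -> %d day(s)", nm,
                                x$extrapolation[[nm]]$n_patients,
                                x$extrapolation[[nm]]$days))
  }
  if (!is.null(x$warning)) lines <- c(lines, paste0("warning: ", x$warning))
  paste(lines, collapse = "\n")
}

#' @export
print.strategy_report <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
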