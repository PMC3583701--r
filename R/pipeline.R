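#' Read a long-format raw-readings CSV with validation
#'
#' Expected columns: `subject_id`, `observer_id`, `visit`, `measure`,
#' `replicate`, `value`, `unit`. A missing column is a schema error and
#' aborts; malformed rows (non-numeric value, unknown measure, unit not
#' matching the measure, replicate outside 1--3) are collected into an
#' error report with their line numbers and excluded from the typed data
#' -- never silently dropped.
#'
#' @param path path to a UTF-8 CSV file with a header row.
#' @return a list with `readings` (typed data frame of valid rows) and
#'   `errors` (data frame with columns `line`, `problem`; line numbers
#'   count the header as line 1).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  required <- c("subject_id", "observer_id", "visit", "measure",
                "replicate", "value", "unit")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  line <- seq_len(nrow(raw)) + 1L  # header is line 1
  value <- suppressWarnings(as.numeric(raw$value))
  replicate <- suppressWarnings(as.integer(raw$replicate))
  problems <- character(nrow(raw))
  bad_value <- is.na(value)
  problems[bad_value] <- sprintf("non-numeric value '%s'",
                                 raw$value[bad_value])
  bad_measure <- !bad_value & !(raw$measure %in% session_measures())
  problems[bad_measure] <- sprintf("unknown measure '%s'",
                                   raw$measure[bad_measure])
  expected_unit <- ifelse(raw$measure == "arm_circumference", "cm", "mm")
  bad_unit <- !bad_value & !bad_measure & raw$unit != expected_unit
  problems[bad_unit] <- sprintf(
    "unit mismatch: '%s' given, '%s' expected for %s",
    raw$unit[bad_unit], expected_unit[bad_unit], raw$measure[bad_unit])
  bad_rep <- !bad_value & !bad_measure & !bad_unit &
    (is.na(replicate) | replicate < 1L | replicate > 3L)
  problems[bad_rep] <- "replicate must be 1, 2 or 3"

  bad <- problems != ""
  readings <- data.frame(
    subject_id = raw$subject_id[!bad],
    observer_id = raw$observer_id[!bad],
    visit = raw$visit[!bad],
    measure = raw$measure[!bad],
    replicate = replicate[!bad],
    value = value[!bad],
    unit = raw$unit[!bad],
    stringsAsFactors = FALSE
  )
  list(
    readings = readings,
    errors = data.frame(line = line[bad], problem = problems[bad],
                        stringsAsFactors = FALSE)
  )
}

#' @rdname read_measurements
#' @details `read_subjects()` reads the companion subject table
#'   (`subject_id`, `height_cm`, `weight_kg`, plus optional demographic
#'   columns) with positivity checks on height and weight.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  subjects <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "height_cm", "weight_kg")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0L) {
    stop("schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(subjects$height_cm)) || any(subjects$height_cm <= 0) ||
      any(!is.finite(subjects$weight_kg)) || any(subjects$weight_kg <= 0)) {
    stop("schema error: height_cm and weight_kg must be positive numbers",
         call. = FALSE)
  }
  subjects
}

# run one pipeline stage, relabelling any error with the stage name
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(name, " stage: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full measurement-to-reliability pipeline
#'
#' Orchestrates the whole analysis: per-session conformance checks, then
#' protocol aggregation of replicate readings, body-fat derivation per
#' observer session, the inter-observer reliability table, and the
#' baseline cohort summary. Deterministic given its inputs; any stage
#' failure aborts with a stage-labelled message.
#'
#' @param readings raw readings: a long-format data frame (see
#'   [read_measurements()]) or a path to its CSV.
#' @param subjects subject table data frame or CSV path.
#' @param out_dir if non-`NULL`, results are written there:
#'   `aggregated.csv`, `bf_percent.csv`, `reliability.csv`,
#'   `reliability.txt` (aligned text table), `baseline_summary.csv`,
#'   `conformance.csv`.
#' @param icc_model,sem_method,descriptors passed to
#'   [reliability_table()].
#' @param denominator passed to the protocol layer (7.5\% rule).
#' @param threshold third-reading trigger threshold (default 0.075).
#' @return (invisibly) a list: `aggregated`, `bf_percent`, `reliability`,
#'   `baseline`, `conformance`, `row_errors`.
#' @export
run_pipeline <- function(readings, subjects, out_dir = NULL,
                         icc_model = c("oneway", "twoway"),
                         sem_method = c("model", "sd_based"),
                         denominator = c("mean", "min", "first"),
                         threshold = 0.075,
                         descriptors = FALSE) {
  icc_model <- match.arg(icc_model)
  sem_method <- match.arg(sem_method)
  denominator <- match.arg(denominator)

  row_errors <- data.frame(line = integer(), problem = character())
  if (is.character(readings)) {
    parsed <- stage("read", read_measurements(readings))
    readings <- parsed$readings
    row_errors <- parsed$errors
  }
  if (is.character(subjects)) {
    subjects <- stage("read", read_subjects(subjects))
  }

  conformance <- stage("conformance", {
    key <- interaction(readings$subject_id, readings$observer_id, drop = TRUE)
    findings <- lapply(split(readings, key), function(s) {
      f <- validate_session(s, threshold, denominator)
      if (nrow(f) > 0L) {
        f$subject_id <- s$subject_id[1]
        f$observer_id <- s$observer_id[1]
      }
      f
    })
    findings <- findings[vapply(findings, nrow, 0L) > 0L]
    if (length(findings) == 0L) {
      data.frame(subject_id = character(), observer_id = character(),
                 measure = character(), finding = character(),
                 detail = character(), stringsAsFactors = FALSE)
    } else {
      out <- do.call(rbind, findings)
      rownames(out) <- NULL
      out[, c("subject_id", "observer_id", "measure", "finding", "detail")]
    }
  })

  aggregated <- stage("aggregate", {
    aggregate_sessions(readings, threshold, denominator)
  })

  bf <- stage("bodyfat", derive_bf_percent(aggregated, subjects))

  reliability <- stage("reliability", {
    tab <- reliability_table(
      rbind(aggregated[, c("subject_id", "observer_id", "measure", "value")],
            bf),
      icc_model = icc_model, sem_method = sem_method,
      descriptors = descriptors)
    if (all(is.na(tab$icc))) {
      stop("no measure has at least 2 subjects with a complete observer pair",
           call. = FALSE)
    }
    tab
  })

  baseline <- stage("summary", summarize_cohort(subjects))

  result <- list(aggregated = aggregated, bf_percent = bf,
                 reliability = reliability, baseline = baseline,
                 conformance = conformance, row_errors = row_errors)

  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      wr <- function(d, f) {
        utils::write.csv(d, file.path(out_dir, f), row.names = FALSE)
      }
      wr(aggregated, "aggregated.csv")
      wr(bf, "bf_percent.csv")
      wr(as.data.frame(unclass(reliability), stringsAsFactors = FALSE),
         "reliability.csv")
      wr(baseline, "baseline_summary.csv")
      wr(conformance, "conformance.csv")
      txt <- utils::capture.output(print(reliability))
      writeLines(txt, file.path(out_dir, "reliability.txt"))
    })
  }
  invisible(result)
}

#' Write a simulated cohort to disk
#'
#' Writes the raw-readings CSV, the subject CSV and a JSON truth record
#' (all generative components with the implied population ICC and SEM per
#' measure) so a simulated study can be re-analysed from files exactly
#' like a real one.
#'
#' @param sim output of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return (invisibly) the paths written.
#' @export
write_cohort <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    readings = file.path(out_dir, "readings.csv"),
    subjects = file.path(out_dir, "subjects.csv"),
    truth = file.path(out_dir, "truth.json")
  )
  utils::write.csv(sim$readings, paths[["readings"]], row.names = FALSE)
  utils::write.csv(sim$subjects, paths[["subjects"]], row.names = FALSE)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(sim$truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  } else {
    writeLines(utils::capture.output(utils::str(sim$truth)), paths[["truth"]])
  }
  invisible(paths)
}
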