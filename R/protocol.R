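#' Does a duplicate pair of readings require a third?
#'
#' Under the measurement protocol two calliper readings are taken at each
#' site; when they differ by more than 7.5\% a third reading must be taken.
#' The protocol literature does not fix the denominator of the relative
#' difference, so it is configurable: the default compares the absolute
#' difference against the mean of the two readings (symmetric, the common
#' anthropometric convention); `"min"` and `"first"` are alternative
#' readings of the rule.
#'
#' The inequality is strict: a pair differing by exactly 7.5\% does not
#' trigger a third reading.
#'
#' @param v1,v2 the two readings, same units, both positive.
#' @param threshold relative-difference threshold (default 0.075).
#' @param denominator what the difference is relative to: `"mean"`
#'   (default), `"min"`, or `"first"`.
#' @return `TRUE` if a third reading is required.
#' @examples
#' needs_third_reading(10.0, 10.5) # FALSE: 4.9% apart
#' needs_third_reading(10.0, 12.0) # TRUE: 18.2% apart
#' @export
needs_third_reading <- function(v1, v2, threshold = 0.075,
                                denominator = c("mean", "min", "first")) {
  denominator <- match.arg(denominator)
  if (length(v1) != 1L || length(v2) != 1L ||
      is.na(v1) || is.na(v2) || !is.numeric(v1) || !is.numeric(v2)) {
    stop("invalid reading: readings must be single non-missing numbers",
         call. = FALSE)
  }
  if (v1 <= 0 || v2 <= 0) {
    stop("invalid reading: readings must be positive", call. = FALSE)
  }
  ref <- switch(denominator,
    mean  = (v1 + v2) / 2,
    min   = min(v1, v2),
    first = v1
  )
  abs(v1 - v2) / ref > threshold
}

#' Aggregate the readings of one site into a single reported value
#'
#' Two readings are reported as their average; three readings (taken when
#' the duplicate pair differed by more than 7.5\%) are reported as their
#' median, none discarded. The aggregated value is rounded half away from
#' zero to one decimal, matching the 0.1 resolution at which readings are
#' recorded.
#'
#' A duplicate pair that needed a third reading but did not get one is
#' aggregated anyway and flagged non-conformant rather than dropped; the
#' caller decides whether to exclude it.
#'
#' @param readings numeric vector of 2 or 3 readings.
#' @inheritParams needs_third_reading
#' @return a list with elements `value` (the aggregated value, 1 dp),
#'   `n_readings_used`, and `conformant` (`FALSE`, with a warning, when a
#'   required third reading is absent).
#' @examples
#' aggregate_readings(c(10.0, 10.4))$value       # 10.2
#' aggregate_readings(c(10.0, 12.0, 11.0))$value # 11.0
#' @export
aggregate_readings <- function(readings, threshold = 0.075,
                               denominator = c("mean", "min", "first")) {
  denominator <- match.arg(denominator)
  n <- length(readings)
  if (n < 2L || n > 3L) {
    stop("protocol violation: expected 2 or 3 readings, got ", n,
         call. = FALSE)
  }
  if (anyNA(readings) || !is.numeric(readings) || any(readings <= 0)) {
    stop("invalid reading: readings must be positive non-missing numbers",
         call. = FALSE)
  }
  conformant <- TRUE
  if (n == 2L) {
    if (needs_third_reading(readings[1], readings[2], threshold, denominator)) {
      conformant <- FALSE
      warning("duplicate readings differ by more than ",
              format(100 * threshold), "% but no third reading was taken",
              call. = FALSE)
    }
    # work in tenths so the halfway case (mean ending in .x5) rounds away
    # from zero exactly, free of binary representation error
    value <- round_half_away(mean(round(readings * 10)), 0) / 10
  } else {
    value <- round_half_away(stats::median(readings), 1)
  }
  list(
    value = value,
    n_readings_used = n,
    conformant = conformant
  )
}

#' Check one observer session for protocol conformance
#'
#' A session is the set of raw readings one observer took on one subject:
#' arm circumference plus the three skinfolds, each with 2--3 replicate
#' readings. Findings are returned, not raised, so non-conformant data can
#' still be processed.
#'
#' Findings reported: skinfold readings outside the 0--80 mm calliper
#' range; any of the four measures absent; fewer than 2 or more than 3
#' readings for a measure; duplicate pairs over the 7.5\% threshold without
#' a third reading.
#'
#' @param session a data frame of raw readings with columns `measure`,
#'   `replicate`, `value` (one subject, one observer).
#' @inheritParams needs_third_reading
#' @return a data frame of findings with columns `measure`, `finding`,
#'   `detail`; zero rows when the session is fully conformant.
#' @export
validate_session <- function(session, threshold = 0.075,
                             denominator = c("mean", "min", "first")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("measure", "value") %in% names(session)))
  findings <- list()
  add <- function(measure, finding, detail) {
    findings[[length(findings) + 1L]] <<-
      data.frame(measure = measure, finding = finding, detail = detail,
                 stringsAsFactors = FALSE)
  }

  for (m in setdiff(session_measures(), unique(session$measure))) {
    add(m, "missing_measure", "no readings recorded for this measure")
  }

  for (m in intersect(session_measures(), unique(session$measure))) {
    vals <- session$value[session$measure == m]
    if (m %in% skinfold_sites()) {
      bad <- vals[vals < CALLIPER_MIN | vals > CALLIPER_MAX]
      for (v in bad) {
        add(m, "range_violation",
            sprintf("reading %.1f mm outside calliper range 0-80 mm", v))
      }
    }
    n <- length(vals)
    if (n < 2L) {
      add(m, "too_few_readings", sprintf("only %d reading(s), need 2-3", n))
    } else if (n > 3L) {
      add(m, "too_many_readings", sprintf("%d readings, maximum is 3", n))
    } else if (n == 2L && all(vals > 0) &&
               needs_third_reading(vals[1], vals[2], threshold, denominator)) {
      add(m, "missing_third_reading",
          sprintf("duplicates (%.1f, %.1f) differ by more than %s%%",
                  vals[1], vals[2], format(100 * threshold)))
    }
  }

  if (length(findings) == 0L) {
    data.frame(measure = character(), finding = character(),
               detail = character(), stringsAsFactors = FALSE)
  } else {
    do.call(rbind, findings)
  }
}

#' Aggregate a long table of raw readings to one value per session measure
#'
#' Applies [aggregate_readings()] to every subject x observer x measure
#' group of a long-format raw-readings table, carrying conformance flags
#' through instead of dropping data.
#'
#' @param readings a data frame with columns `subject_id`, `observer_id`,
#'   `measure`, `replicate`, `value` (and optionally `visit`, `unit`).
#' @inheritParams needs_third_reading
#' @return a data frame with one row per subject x observer x measure:
#'   columns `subject_id`, `observer_id`, `measure`, `value`,
#'   `n_readings_used`, `conformant`.
#' @export
aggregate_sessions <- function(readings, threshold = 0.075,
                               denominator = c("mean", "min", "first")) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("subject_id", "observer_id", "measure", "value") %in%
                  names(readings)))
  key <- interaction(readings$subject_id, readings$observer_id,
                     readings$measure, drop = TRUE)
  first <- !duplicated(key)
  groups <- split(readings$value, key)
  agg <- lapply(groups, function(v) {
    withCallingHandlers(
      aggregate_readings(v, threshold, denominator),
      warning = function(w) invokeRestart("muffleWarning")
    )
  })
  ord_key <- match(levels(key), key[first])
  out <- data.frame(
    subject_id = readings$subject_id[first][ord_key],
    observer_id = readings$observer_id[first][ord_key],
    measure = readings$measure[first][ord_key],
    value = vapply(agg, `[[`, 0, "value"),
    n_readings_used = vapply(agg, `[[`, 0L, "n_readings_used"),
    conformant = vapply(agg, `[[`, NA, "conformant"),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$subject_id, out$observer_id, out$measure), , drop = FALSE]
}
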