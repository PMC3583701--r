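#' One-way random-effects ANOVA decomposition for paired observer data
#'
#' Decomposes dual-observer measurements into between-subject and
#' within-subject mean squares. This is the variance-components engine
#' behind the random-observer reliability model: when each subject is
#' rated by a (possibly different) random pair of observers, observer
#' effects are absorbed into the within-subject term.
#'
#' With n subjects each measured k times,
#' MS_between = k * sum_i (ybar_i - ybar)^2 / (n - 1) and
#' MS_within = sum_ij (y_ij - ybar_i)^2 / (n (k - 1)).
#'
#' @param data a data frame with columns `subject_id` and `value`; every
#'   subject must contribute the same number k >= 2 of values.
#' @return a list of class `anova_decomposition`: `ms_between`,
#'   `ms_within`, `ss_between`, `ss_within`, `ss_total`, `n_subjects`, `k`,
#'   `grand_mean`.
#' @export
anova_one_way <- function(data) {
  stopifnot(all(c("subject_id", "value") %in% names(data)))
  if (anyNA(data$value)) {
    stop("missing values within subjects are not allowed", call. = FALSE)
  }
  counts <- table(data$subject_id)
  n <- length(counts)
  if (n < 2L) {
    stop("need at least 2 subjects", call. = FALSE)
  }
  k <- unique(as.integer(counts))
  if (length(k) != 1L || k < 2L) {
    stop("every subject must contribute the same number (>= 2) of values",
         call. = FALSE)
  }
  grand <- mean(data$value)
  subj_means <- tapply(data$value, data$subject_id, mean)
  ss_between <- k * sum((subj_means - grand)^2)
  ss_within <- sum((data$value - subj_means[as.character(data$subject_id)])^2)
  structure(
    list(
      ms_between = ss_between / (n - 1),
      ms_within = ss_within / (n * (k - 1)),
      ss_between = ss_between,
      ss_within = ss_within,
      ss_total = sum((data$value - grand)^2),
      n_subjects = n,
      k = k,
      grand_mean = grand
    ),
    class = "anova_decomposition"
  )
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' The single-measure ICC for designs where each subject is measured by a
#' random set of observers that need not be the same across subjects:
#' ICC(1) = (MS_between - MS_within) / (MS_between + (k-1) MS_within).
#' The estimate may be negative for small samples with little subject
#' signal; it is reported as computed, never truncated.
#'
#' @inheritParams anova_one_way
#' @return the ICC estimate, a number in (-1/(k-1), 1].
#' @examples
#' d <- data.frame(subject_id = rep(1:4, each = 2),
#'                 value = c(10, 10, 12, 12, 15, 15, 9, 9))
#' icc_oneway(d) # 1: perfect duplicate agreement
#' @export
icc_oneway <- function(data) {
  a <- anova_one_way(data)
  denom <- a$ms_between + (a$k - 1) * a$ms_within
  if (denom == 0) {
    stop("ICC undefined: all values are identical", call. = FALSE)
  }
  (a$ms_between - a$ms_within) / denom
}

#' Standard error of measurement from the random-observer model
#'
#' The model-based SEM is the square root of the within-subject mean
#' square: the standard deviation expected across repeated measurements of
#' the same subject by different observers, in the measure's own units.
#' The classical alternative SD * sqrt(1 - ICC) (total sample SD deflated
#' by the reliability) is available via `method = "sd_based"`.
#'
#' @inheritParams anova_one_way
#' @param method `"model"` (default, sqrt(MS_within)) or `"sd_based"`.
#' @return the SEM, a non-negative number in measurement units.
#' @export
sem_from_model <- function(data, method = c("model", "sd_based")) {
  method <- match.arg(method)
  a <- anova_one_way(data)
  if (method == "model") {
    sqrt(a$ms_within)
  } else {
    stats::sd(data$value) * sqrt(1 - icc_oneway(data))
  }
}

#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' The single-measure ICC for fully crossed designs in which the same
#' random panel of k observers measures every subject, separating observer
#' variance from residual error:
#' ICC(2,1) = (MS_R - MS_E) / (MS_R + (k-1) MS_E + k (MS_C - MS_E)/n),
#' with MS_R the subject (row), MS_C the observer (column) and MS_E the
#' interaction/error mean squares of the two-way decomposition.
#'
#' Requires a fully crossed design: if any observer did not measure every
#' subject the observer and error components are not separable here and an
#' estimability error is raised (use [icc_oneway()] for such designs).
#'
#' @param data a data frame with columns `subject_id`, `observer_id`,
#'   `value`; one value per subject x observer cell, all cells present.
#' @return the ICC(2,1) estimate.
#' @export
icc_twoway_random <- function(data) {
  stopifnot(all(c("subject_id", "observer_id", "value") %in% names(data)))
  if (anyNA(data$value)) {
    stop("missing values are not allowed", call. = FALSE)
  }
  tab <- table(data$subject_id, data$observer_id)
  if (any(tab != 1L)) {
    stop("estimability error: ICC(2,1) needs a fully crossed design ",
         "(every observer measuring every subject exactly once)",
         call. = FALSE)
  }
  n <- nrow(tab)
  k <- ncol(tab)
  if (n < 2L || k < 2L) {
    stop("need at least 2 subjects and 2 observers", call. = FALSE)
  }
  grand <- mean(data$value)
  subj_means <- tapply(data$value, data$subject_id, mean)
  obs_means <- tapply(data$value, data$observer_id, mean)
  ms_r <- k * sum((subj_means - grand)^2) / (n - 1)
  ms_c <- n * sum((obs_means - grand)^2) / (k - 1)
  resid <- data$value -
    subj_means[as.character(data$subject_id)] -
    obs_means[as.character(data$observer_id)] + grand
  ms_e <- sum(resid^2) / ((n - 1) * (k - 1))
  denom <- ms_r + (k - 1) * ms_e + k * (ms_c - ms_e) / n
  if (denom == 0) {
    stop("ICC undefined: all values are identical", call. = FALSE)
  }
  (ms_r - ms_e) / denom
}

#' Classify an ICC into reliability bands
#'
#' The canonical two-band classification: ICC of 0--0.75 indicates poor to
#' moderate reliability, above 0.75 good reliability (boundary inclusive
#' below). Negative estimates are classed poor-to-moderate and flagged.
#' An optional verbal descriptor layer (<= 0.6 moderate, 0.6--0.9 good,
#' > 0.9 excellent) is off by default because such labels vary between
#' reports; the two bands are the standard.
#'
#' @param icc ICC estimate(s), each <= 1 (vectorised).
#' @param descriptors if `TRUE`, add the verbal descriptor layer.
#' @return a data frame with columns `icc`, `band`
#'   (`"poor_to_moderate"`/`"good"`), `sub_zero` (logical), and
#'   `descriptor` when requested.
#' @examples
#' classify_icc(c(0.97, 0.56, 0.75))$band
#' @export
classify_icc <- function(icc, descriptors = FALSE) {
  stopifnot(is.numeric(icc), all(is.finite(icc)))
  if (any(icc > 1)) stop("ICC cannot exceed 1", call. = FALSE)
  out <- data.frame(
    icc = icc,
    band = ifelse(icc > 0.75, "good", "poor_to_moderate"),
    sub_zero = icc < 0,
    stringsAsFactors = FALSE
  )
  if (descriptors) {
    out$descriptor <- ifelse(icc > 0.9, "excellent",
                             ifelse(icc > 0.6, "good", "moderate"))
  }
  out
}

# Build the paired (k = 2) set for one measure from aggregated data,
# excluding subjects without exactly 2 distinct-observer values for that
# measure (pairwise per-measure exclusion). Returns NULL if < 2 subjects.
paired_measure_set <- function(aggregated, measure, k = 2L) {
  d <- aggregated[aggregated$measure == measure,
                  c("subject_id", "observer_id", "value")]
  if (nrow(d) == 0L) return(NULL)
  ok <- names(which(tapply(d$observer_id, d$subject_id,
                           function(o) length(unique(o)) == k &&
                             length(o) == k)))
  d <- d[d$subject_id %in% ok, , drop = FALSE]
  if (length(unique(d$subject_id)) < 2L) return(NULL)
  d
}

#' Inter-observer reliability table across all measures
#'
#' Builds the reliability report: one row per measure (the four session
#' measures plus derived body fat percentage when present) with the
#' average and range over all observers and women, the SEM, the ICC, and
#' the reliability band. Subjects lacking a complete observer pair for a
#' measure are excluded for that measure only; a measure with fewer than
#' 2 usable subjects is reported as an absent row (NA statistics), not a
#' failure. Statistics are computed at full precision; rounding is left to
#' the print method.
#'
#' @param aggregated aggregated measurements: data frame with columns
#'   `subject_id`, `observer_id`, `measure`, `value` (e.g. output of
#'   [aggregate_sessions()], optionally with [derive_bf_percent()] rows
#'   appended).
#' @param measures measures to report, in row order.
#' @param icc_model `"oneway"` (default, random observers absorbed into
#'   error) or `"twoway"` (crossed panel, ICC(2,1)).
#' @param sem_method passed to [sem_from_model()].
#' @param descriptors passed to [classify_icc()].
#' @return a data frame of class `reliability_table` with columns
#'   `measure`, `unit`, `n_subjects`, `average`, `range_min`, `range_max`,
#'   `sem`, `icc`, `band` (and `descriptor` if requested).
#' @export
reliability_table <- function(aggregated,
                              measures = c(session_measures(), "bf_percent"),
                              icc_model = c("oneway", "twoway"),
                              sem_method = c("model", "sd_based"),
                              descriptors = FALSE) {
  icc_model <- match.arg(icc_model)
  sem_method <- match.arg(sem_method)
  rows <- lapply(measures, function(m) {
    empty <- data.frame(measure = m, unit = measure_unit(m),
                        n_subjects = 0L, average = NA_real_,
                        range_min = NA_real_, range_max = NA_real_,
                        sem = NA_real_, icc = NA_real_,
                        band = NA_character_, stringsAsFactors = FALSE)
    d <- paired_measure_set(aggregated, m)
    if (is.null(d)) return(empty)
    icc <- if (icc_model == "oneway") icc_oneway(d) else icc_twoway_random(d)
    cls <- classify_icc(icc, descriptors = descriptors)
    out <- data.frame(
      measure = m,
      unit = measure_unit(m),
      n_subjects = length(unique(d$subject_id)),
      average = mean(d$value),
      range_min = min(d$value),
      range_max = max(d$value),
      sem = sem_from_model(d, sem_method),
      icc = icc,
      band = cls$band,
      stringsAsFactors = FALSE
    )
    if (descriptors) out$descriptor <- cls$descriptor
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("reliability_table", class(out))
  out
}

#' @export
print.reliability_table <- function(x, ...) {
  fmt <- function(v, d = 2) ifelse(is.na(v), "-", sprintf(paste0("%.", d, "f"), v))
  disp <- data.frame(
    Measure = paste0(x$measure, " (", x$unit, ")"),
    `Average (Range)` = ifelse(
      is.na(x$average), "-",
      sprintf("%s (%s-%s)", fmt(x$average), fmt(x$range_min), fmt(x$range_max))
    ),
    SEM = fmt(x$sem),
    ICC = fmt(x$icc),
    Band = ifelse(is.na(x$band), "-", x$band),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' Baseline cohort summary
#'
#' Descriptive summary of the subject table in the style of a baseline
#' characteristics table: mean (SD) for age, median (IQR) for gestational
#' age at entry and BMI, and N (\%) for nulliparity, smoking, ethnicity
#' and BMI category. With a single subject the SD is undefined and
#' reported as not available.
#'
#' @param subjects subject table with columns `subject_id`, `age`,
#'   `gestational_age_weeks`, `bmi` (or `height_cm` + `weight_kg` from
#'   which BMI is computed), `parity`, `smoker`, `ethnicity`.
#' @return a data frame with columns `characteristic`, `statistic`,
#'   `est1`, `est2` (the two numbers of each summary: mean/SD, median/IQR
#'   bounds collapse to Q1 in est1 and Q3 in est2, count/percent), and
#'   `display` (formatted text).
#' @export
summarize_cohort <- function(subjects) {
  stopifnot(nrow(subjects) >= 1L)
  if (!"bmi" %in% names(subjects)) {
    subjects$bmi <- compute_bmi(subjects$weight_kg, subjects$height_cm / 100)
  }
  n <- nrow(subjects)
  rows <- list()
  add <- function(characteristic, statistic, est1, est2, display) {
    rows[[length(rows) + 1L]] <<- data.frame(
      characteristic = characteristic, statistic = statistic,
      est1 = est1, est2 = est2, display = display, stringsAsFactors = FALSE)
  }
  mean_sd <- function(x, lab, d = 1) {
    m <- mean(x)
    s <- if (length(x) > 1L) stats::sd(x) else NA_real_
    add(lab, "mean_sd", m, s,
        sprintf("%.*f (%s)", d, m,
                if (is.na(s)) "not available" else sprintf("%.*f", d, s)))
  }
  med_iqr <- function(x, lab, d = 1) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    add(lab, "median_iqr", q[1], q[3],
        sprintf("%.*f (%.*f-%.*f)", d, q[2], d, q[1], d, q[3]))
  }
  n_pct <- function(cnt, lab) {
    add(lab, "n_percent", cnt, 100 * cnt / n,
        sprintf("%d (%.1f)", cnt, 100 * cnt / n))
  }

  mean_sd(subjects$age, "Maternal age (years): mean (SD)")
  if ("gestational_age_weeks" %in% names(subjects)) {
    med_iqr(subjects$gestational_age_weeks,
            "Gestational age at entry (weeks): median (IQR)")
  }
  if ("parity" %in% names(subjects)) {
    n_pct(sum(subjects$parity == 0), "Parity 0: N (%)")
  }
  if ("smoker" %in% names(subjects)) {
    n_pct(sum(subjects$smoker), "Smoker: N (%)")
  }
  if ("ethnicity" %in% names(subjects)) {
    main <- names(sort(table(subjects$ethnicity), decreasing = TRUE))[1]
    n_pct(sum(subjects$ethnicity == main),
          sprintf("Ethnicity %s: N (%%)", main))
  }
  med_iqr(subjects$bmi, "BMI (kg/m2): median (IQR)")
  cat_ <- classify_bmi(subjects$bmi)
  n_pct(sum(cat_ == "overweight"), "BMI 25.0-29.9: N (%)")
  n_pct(sum(cat_ == "obese"), "BMI >= 30.0: N (%)")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
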