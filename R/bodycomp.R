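#' Body mass index
#'
#' BMI = weight (kg) / height (m)^2, reported to one decimal place.
#'
#' @param weight_kg body weight in kilograms, positive.
#' @param height_m standing height in metres, positive. Height enters BMI
#'   in metres but the body-fat equation in centimetres; the argument names
#'   make the unit explicit at every call site.
#' @return BMI in kg/m^2, rounded to 1 dp.
#' @examples
#' compute_bmi(80, 1.655) # 29.2
#' @export
compute_bmi <- function(weight_kg, height_m) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_m)) ||
      any(weight_kg <= 0) || any(height_m <= 0)) {
    stop("weight and height must be positive", call. = FALSE)
  }
  round_half_away(weight_kg / height_m^2, 1)
}

#' WHO BMI category for an overweight/obese cohort
#'
#' WHO bands as used for cohort eligibility: overweight 25.0--29.9 kg/m^2,
#' obese >= 30.0 kg/m^2. Values below 25.0 are outside the cohort and
#' labelled `below_cohort`.
#'
#' @param bmi BMI in kg/m^2 (vectorised).
#' @return character vector: `"overweight"`, `"obese"`, or
#'   `"below_cohort"`.
#' @examples
#' classify_bmi(c(24.9, 29.9, 30.0))
#' @export
classify_bmi <- function(bmi) {
  stopifnot(is.numeric(bmi), all(is.finite(bmi)))
  ifelse(bmi >= 30, "obese",
         ifelse(bmi >= 25, "overweight", "below_cohort"))
}

# coefficients of the body-fat prediction equation (skinfolds in mm,
# height and arm circumference in cm)
BF_COEF <- c(
  intercept = 12.7,
  triceps = 0.457,
  subscapular = 0.352,
  biceps = 0.103,
  height = -0.057,
  arm_circumference = 0.265
)

#' Body fat percentage from anthropometric measurements
#'
#' Linear prediction equation for body fat percentage in overweight and
#' obese pregnant women:
#'
#' BF\% = 12.7 + 0.457 triceps + 0.352 subscapular + 0.103 biceps
#'        - 0.057 height + 0.265 arm circumference
#'
#' with skinfolds in mm and height and arm circumference in cm. The
#' coefficients are taken as given (derived and validated externally on
#' samples of 721 and 481 women); the equation is unbounded, so a warning
#' fires when the prediction falls outside the plausible 5--60\% band.
#'
#' @param triceps_mm,subscapular_mm,biceps_mm skinfold thicknesses, mm.
#' @param height_cm standing height, cm (note: centimetres here, metres in
#'   [compute_bmi()]).
#' @param arm_circumference_cm mid-upper-arm circumference, cm.
#' @param digits decimals to report (default 2; use `NULL` for full
#'   precision).
#' @return predicted body fat percentage. Vectorised over all inputs.
#' @examples
#' body_fat_percent(24.13, 25.37, 13.21, 165.25, 34.57) # 33.76
#' @export
body_fat_percent <- function(triceps_mm, subscapular_mm, biceps_mm,
                             height_cm, arm_circumference_cm, digits = 2) {
  args <- list(triceps_mm, subscapular_mm, biceps_mm, height_cm,
               arm_circumference_cm)
  if (any(vapply(args, function(a) any(!is.finite(a)), logical(1)))) {
    stop("all body-fat inputs must be present and finite", call. = FALSE)
  }
  if (any(triceps_mm < 0) || any(subscapular_mm < 0) || any(biceps_mm < 0) ||
      any(height_cm < 0) || any(arm_circumference_cm < 0)) {
    stop("body-fat inputs must be non-negative", call. = FALSE)
  }
  if (any(c(triceps_mm, subscapular_mm, biceps_mm) > CALLIPER_MAX)) {
    stop("skinfold inputs exceed the 80 mm calliper range", call. = FALSE)
  }
  bf <- BF_COEF[["intercept"]] +
    BF_COEF[["triceps"]] * triceps_mm +
    BF_COEF[["subscapular"]] * subscapular_mm +
    BF_COEF[["biceps"]] * biceps_mm +
    BF_COEF[["height"]] * height_cm +
    BF_COEF[["arm_circumference"]] * arm_circumference_cm
  if (any(bf < 5 | bf > 60)) {
    warning("body fat percentage outside the plausible 5-60% band",
            call. = FALSE)
  }
  if (is.null(digits)) bf else round_half_away(bf, digits)
}

#' Per-observer body fat percentage from aggregated session measurements
#'
#' Joins the aggregated measurements (output of [aggregate_sessions()])
#' with the subject table and computes BF\% once per subject x observer
#' session, so inter-observer variability in the skinfolds propagates into
#' BF\%. Sessions missing any of the four measures are skipped.
#'
#' @param aggregated data frame from [aggregate_sessions()].
#' @param subjects subject table with columns `subject_id`, `height_cm`.
#' @return data frame with columns `subject_id`, `observer_id`, `measure`
#'   (`"bf_percent"`), `value` -- same shape as `aggregated`, ready to be
#'   appended as a derived measure.
#' @export
derive_bf_percent <- function(aggregated, subjects) {
  stopifnot(all(c("subject_id", "height_cm") %in% names(subjects)))
  wide <- stats::reshape(
    aggregated[, c("subject_id", "observer_id", "measure", "value")],
    idvar = c("subject_id", "observer_id"),
    timevar = "measure", direction = "wide"
  )
  names(wide) <- sub("^value\\.", "", names(wide))
  need <- session_measures()
  missing_cols <- setdiff(need, names(wide))
  for (m in missing_cols) wide[[m]] <- NA_real_
  wide <- merge(wide, subjects[, c("subject_id", "height_cm")],
                by = "subject_id")
  complete <- stats::complete.cases(wide[, c(need, "height_cm")])
  wide <- wide[complete, , drop = FALSE]
  if (nrow(wide) == 0L) {
    return(data.frame(subject_id = character(), observer_id = character(),
                      measure = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    subject_id = wide$subject_id,
    observer_id = wide$observer_id,
    measure = "bf_percent",
    value = body_fat_percent(wide$triceps, wide$subscapular, wide$biceps,
                             wide$height_cm, wide$arm_circumference,
                             digits = NULL),
    stringsAsFactors = FALSE
  )
}
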