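#' Measurement sites and units
#'
#' The measurement session records four anthropometric measures: arm
#' circumference (a girth, in cm) and three calliper skinfold thicknesses
#' (biceps, triceps, subscapular, in mm). Body fat percentage is a derived
#' fifth measure computed downstream from these four plus height.
#'
#' @return `skinfold_sites()` returns the three skinfold site labels;
#'   `session_measures()` the four measures recorded at a session;
#'   `measure_unit()` the unit string ("mm" or "cm") for a measure.
#' @examples
#' skinfold_sites()
#' measure_unit("arm_circumference")
#' @export
skinfold_sites <- function() {
  c("biceps", "triceps", "subscapular")
}

#' @rdname skinfold_sites
#' @export
session_measures <- function() {
  c("arm_circumference", "biceps", "triceps", "subscapular")
}

#' @rdname skinfold_sites
#' @param measure a measure label from `session_measures()` or
#'   `"bf_percent"`.
#' @export
measure_unit <- function(measure) {
  measure <- match.arg(measure, c(session_measures(), "bf_percent"))
  switch(measure,
    arm_circumference = "cm",
    bf_percent = "%",
    "mm"
  )
}

# Harpenden calliper measuring range, mm
CALLIPER_MIN <- 0
CALLIPER_MAX <- 80

# Round half away from zero at the given number of decimals. base::round()
# rounds half to even, which is not how field values are recorded.
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
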