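test_that("the 7.5% rule triggers on large relative differences only", {
  expect_false(needs_third_reading(10.0, 10.5)) # 4.9% of the pair mean
  expect_false(needs_third_reading(10.0, 10.0))
  expect_true(needs_third_reading(10.0, 12.0))  # 18.2% of the pair mean
})

test_that("the 7.5% rule is strict at the threshold", {
  # 0.75/10 is exactly 7.5% of the first reading: no third reading
  expect_false(needs_third_reading(10.0, 10.75, denominator = "first"))
  expect_false(needs_third_reading(10.0, 10.75, denominator = "min"))
  expect_true(needs_third_reading(10.0, 10.76, denominator = "first"))
})

test_that("the 7.5% rule is symmetric, scale-invariant and reflexive-false", {
  set.seed(41)
  for (i in 1:50) {
    a <- runif(1, 1, 60)
    b <- a * runif(1, 0.8, 1.25)
    k <- runif(1, 0.1, 10)
    expect_identical(needs_third_reading(a, b), needs_third_reading(b, a))
    expect_identical(needs_third_reading(k * a, k * b),
                     needs_third_reading(a, b))
    expect_false(needs_third_reading(a, a))
  }
})

test_that("alternative denominators give a more conservative rule", {
  # min and first denominators are <= mean, so they trigger at least as often
  expect_false(needs_third_reading(10.0, 10.7, denominator = "mean"))
  expect_false(needs_third_reading(10.0, 10.7, denominator = "min"))
  expect_true(needs_third_reading(10.0, 10.8, denominator = "min"))
})

test_that("invalid readings are rejected", {
  expect_error(needs_third_reading(0, 10), "invalid reading")
  expect_error(needs_third_reading(10, -1), "invalid reading")
  expect_error(needs_third_reading(NA_real_, 10), "invalid reading")
  expect_error(aggregate_readings(c(10, NA)), "invalid reading")
})

test_that("two readings aggregate to their mean, three to their median", {
  expect_equal(aggregate_readings(c(10.0, 10.4))$value, 10.2)
  expect_equal(aggregate_readings(c(10.0, 12.0, 11.0))$value, 11.0)
  expect_equal(aggregate_readings(c(13.2, 13.2, 13.2))$value, 13.2)
  expect_equal(aggregate_readings(c(10.0, 10.4))$n_readings_used, 2)
  expect_equal(aggregate_readings(c(10.0, 12.0, 11.0))$n_readings_used, 3)
})

test_that("aggregation rounds halves away from zero at 0.1 resolution", {
  # mean of 10.1 and 10.2 is 10.15, which must report as 10.2
  expect_equal(aggregate_readings(c(10.1, 10.2))$value, 10.2)
  expect_equal(aggregate_readings(c(10.3, 10.4))$value, 10.4)
})

test_that("aggregation is permutation-invariant and bounded by min/max", {
  set.seed(42)
  for (i in 1:50) {
    v <- round(runif(sample(2:3, 1), 5, 40), 1)
    ref <- suppressWarnings(aggregate_readings(v)$value)
    for (p in list(rev(v), sample(v))) {
      expect_equal(suppressWarnings(aggregate_readings(p)$value), ref)
    }
    expect_gte(ref, min(v))
    expect_lte(ref, max(v))
    # identical readings aggregate to that reading
    expect_equal(aggregate_readings(rep(v[1], length(v)))$value, v[1])
  }
})

test_that("wrong reading counts are protocol violations", {
  expect_error(aggregate_readings(10.0), "protocol violation")
  expect_error(aggregate_readings(c(10, 11, 12, 13)), "protocol violation")
})

test_that("a discrepant pair without a third reading is kept but flagged", {
  expect_warning(res <- aggregate_readings(c(10.0, 12.0)), "third reading")
  expect_equal(res$value, 11.0)
  expect_false(res$conformant)
  expect_true(aggregate_readings(c(10.0, 10.4))$conformant)
})

test_that("a fully conformant session yields no findings", {
  expect_identical(nrow(validate_session(make_session())), 0L)
})

test_that("validate_session reports range, completeness and third-reading findings", {
  s <- make_session()
  s$value[s$measure == "subscapular"] <- c(81.0, 25.6)
  f <- validate_session(s)
  expect_true("range_violation" %in% f$finding)

  s2 <- make_session()[make_session()$measure != "biceps", ]
  f2 <- validate_session(s2)
  expect_true(any(f2$finding == "missing_measure" & f2$measure == "biceps"))

  s3 <- make_session()
  s3$value[s3$measure == "triceps"] <- c(10.0, 12.0)
  f3 <- validate_session(s3)
  expect_true(any(f3$finding == "missing_third_reading" &
                    f3$measure == "triceps"))

  s4 <- rbind(make_session(),
              data.frame(subject_id = "S1", observer_id = "obs1",
                         visit = "entry", measure = "triceps",
                         replicate = 3:4, value = c(24.1, 24.2),
                         unit = "mm", stringsAsFactors = FALSE))
  expect_true(any(validate_session(s4)$finding == "too_many_readings"))
})

test_that("aggregate_sessions aggregates each subject x observer x measure group", {
  s <- rbind(make_session("S1", "obs1"), make_session("S1", "obs2"),
             make_session("S2", "obs1"))
  agg <- aggregate_sessions(s)
  expect_equal(nrow(agg), 12)
  expect_true(all(agg$conformant))
  one <- agg[agg$subject_id == "S1" & agg$observer_id == "obs1" &
               agg$measure == "triceps", ]
  expect_equal(one$value, 24.2)
  expect_equal(one$n_readings_used, 2)
})
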