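test_that("one-way ANOVA handles the degenerate corner cases", {
  perfect <- data.frame(subject_id = rep(c("A", "B"), each = 2),
                        value = c(1, 1, 2, 2))
  a <- anova_one_way(perfect)
  expect_equal(a$ms_within, 0)
  expect_gt(a$ms_between, 0)

  no_signal <- data.frame(subject_id = rep(c("A", "B"), each = 2),
                          value = c(0, 2, 2, 0))
  expect_equal(anova_one_way(no_signal)$ms_between, 0)
})

test_that("one-way ANOVA matches the brute-force oracle on a fixed table", {
  d <- fixed_paired_table()
  a <- anova_one_way(d)
  o <- oracle_oneway(d$subject_id, d$value)
  expect_equal(a$ms_between, o$ms_between, tolerance = 1e-12)
  expect_equal(a$ms_within, o$ms_within, tolerance = 1e-12)
  # ANOVA identity: partitioned sums of squares add to the total
  expect_equal(a$ss_between + a$ss_within, a$ss_total, tolerance = 1e-10)
})

test_that("one-way mean squares agree with stats::aov", {
  d <- fixed_paired_table()
  fit <- summary(stats::aov(value ~ factor(subject_id), data = d))[[1]]
  a <- anova_one_way(d)
  expect_equal(a$ms_between, fit["factor(subject_id)", "Mean Sq"],
               tolerance = 1e-10)
  expect_equal(a$ms_within, fit["Residuals", "Mean Sq"], tolerance = 1e-10)
})

test_that("shape violations are rejected", {
  expect_error(anova_one_way(data.frame(subject_id = "A", value = 1:2)),
               "at least 2 subjects")
  expect_error(
    anova_one_way(data.frame(subject_id = c("A", "A", "B"), value = 1:3)),
    "same number")
  expect_error(
    anova_one_way(data.frame(subject_id = rep(c("A", "B"), each = 2),
                             value = c(1, NA, 2, 2))),
    "missing")
})

test_that("ICC(1,1) is 1 for perfect agreement and -0.5 on the anti-correlated table", {
  perfect <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                        value = c(10, 10, 14, 14, 18, 18))
  expect_equal(icc_oneway(perfect), 1)

  anti <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                     value = c(0, 2, 2, 0, 1, 3))
  expect_equal(icc_oneway(anti), -0.5, tolerance = 1e-12)
  expect_equal(icc_oneway(anti), oracle_oneway(anti$subject_id, anti$value)$icc,
               tolerance = 1e-12)

  flat <- data.frame(subject_id = rep(c("A", "B"), each = 2), value = rep(5, 4))
  expect_error(icc_oneway(flat), "identical")
})

test_that("ICC(1,1) and SEM match the brute-force oracle on random small instances", {
  set.seed(123)
  for (i in 1:60) {
    d <- random_paired_set(sample(2:10, 1))
    o <- oracle_oneway(d$subject_id, d$value)
    expect_equal(icc_oneway(d), o$icc, tolerance = 1e-10)
    expect_equal(sem_from_model(d), o$sem, tolerance = 1e-10)
  }
})

test_that("ICC estimates the population variance ratio at large n", {
  set.seed(202)
  # sigma2_subject = 3, sigma2_error = 1: population ICC 0.75, SEM 1
  d <- random_paired_set(5000, sd_subject = sqrt(3), sd_error = 1)
  expect_equal(icc_oneway(d), 0.75, tolerance = 0.02)
  expect_equal(sem_from_model(d), 1.0, tolerance = 0.05)
})

test_that("SEM is the within-subject error SD", {
  perfect <- data.frame(subject_id = rep(c("A", "B"), each = 2),
                        value = c(1, 1, 2, 2))
  expect_equal(sem_from_model(perfect), 0)

  d <- fixed_paired_table()
  expect_equal(sem_from_model(d),
               sqrt(oracle_oneway(d$subject_id, d$value)$ms_within),
               tolerance = 1e-12)

  set.seed(31)
  big <- random_paired_set(5000, sd_subject = 2, sd_error = 3)
  expect_equal(sem_from_model(big), 3.0, tolerance = 0.05)
})

test_that("the sd-based SEM alternative equals SD * sqrt(1 - ICC)", {
  d <- fixed_paired_table()
  expect_equal(sem_from_model(d, method = "sd_based"),
               sd(d$value) * sqrt(1 - icc_oneway(d)), tolerance = 1e-12)
})

test_that("ICC is location/scale invariant; SEM scales", {
  d <- fixed_paired_table()
  shifted <- transform(d, value = value + 13.7)
  scaled <- transform(d, value = value * 2.5)
  expect_equal(icc_oneway(shifted), icc_oneway(d), tolerance = 1e-10)
  expect_equal(icc_oneway(scaled), icc_oneway(d), tolerance = 1e-10)
  expect_equal(sem_from_model(shifted), sem_from_model(d), tolerance = 1e-10)
  expect_equal(sem_from_model(scaled), 2.5 * sem_from_model(d),
               tolerance = 1e-10)
})

test_that("ICC(2,1) approaches ICC(1,1) when observer variance is zero", {
  set.seed(55)
  d <- random_paired_set(5000, sd_subject = 2, sd_error = 1)
  expect_equal(icc_twoway_random(d), icc_oneway(d), tolerance = 5e-3)
})

test_that("a constant observer offset enters the ICC(2,1) denominator", {
  d <- fixed_paired_table()
  off <- d
  off$value[off$observer_id == "obs2"] <-
    off$value[off$observer_id == "obs2"] + 2.0
  # the offset is pure observer variance: it lowers ICC(2,1) relative to
  # the unshifted data, and more strongly lowers ICC(1,1), which absorbs
  # the whole offset into error
  expect_lt(icc_twoway_random(off), icc_twoway_random(d))
  expect_lt(icc_oneway(off), icc_oneway(d))
  expect_lt(icc_oneway(off), icc_oneway(d) - 0.01)
})

test_that("ICC(2,1) is 1 for perfect agreement and needs a crossed design", {
  perfect <- data.frame(subject_id = rep(c("A", "B", "C"), each = 2),
                        observer_id = rep(c("obs1", "obs2"), 3),
                        value = c(10, 10, 14, 14, 18, 18))
  expect_equal(icc_twoway_random(perfect), 1)

  sparse <- perfect
  sparse$observer_id[2] <- "obs3"
  expect_error(icc_twoway_random(sparse), "estimability")
})

test_that("ICC bands use the 0.75 cut, boundary inclusive below", {
  expect_equal(classify_icc(0.97)$band, "good")
  expect_equal(classify_icc(0.56)$band, "poor_to_moderate")
  expect_equal(classify_icc(0.75)$band, "poor_to_moderate")
  expect_equal(classify_icc(0.76)$band, "good")
  neg <- classify_icc(-0.2)
  expect_equal(neg$band, "poor_to_moderate")
  expect_true(neg$sub_zero)
  expect_error(classify_icc(1.2), "exceed")
})

test_that("classification is monotone in the ICC", {
  grid <- seq(-0.4, 1, by = 0.05)
  ranks <- ifelse(classify_icc(grid)$band == "good", 2, 1)
  expect_true(all(diff(ranks) >= 0))
})

test_that("verbal descriptors follow the optional sub-bands", {
  d <- classify_icc(c(0.5, 0.7, 0.95), descriptors = TRUE)
  expect_equal(d$descriptor, c("moderate", "good", "excellent"))
  expect_false("descriptor" %in% names(classify_icc(0.5)))
})

test_that("the reliability table reports one row per measure with pairwise exclusion", {
  agg <- rbind(
    data.frame(subject_id = rep(sprintf("S%d", 1:6), each = 2),
               observer_id = rep(c("obs1", "obs2"), 6),
               measure = "triceps",
               value = fixed_paired_table()$value,
               stringsAsFactors = FALSE),
    # biceps missing its second observer for S6: that subject drops out
    data.frame(subject_id = c(rep(sprintf("S%d", 1:5), each = 2), "S6"),
               observer_id = c(rep(c("obs1", "obs2"), 5), "obs1"),
               measure = "biceps",
               value = c(fixed_paired_table()$value[1:10], 12.0),
               stringsAsFactors = FALSE)
  )
  tab <- reliability_table(agg, measures = c("triceps", "biceps", "subscapular"))
  expect_equal(tab$measure, c("triceps", "biceps", "subscapular"))
  expect_equal(tab$n_subjects, c(6L, 5L, 0L))
  expect_true(is.na(tab$icc[3])) # absent measure: NA row, not an error
  d <- fixed_paired_table()
  expect_equal(tab$icc[1], icc_oneway(d), tolerance = 1e-12)
  expect_equal(tab$sem[1], sem_from_model(d), tolerance = 1e-12)
  expect_equal(tab$average[1], mean(d$value), tolerance = 1e-12)
  expect_equal(c(tab$range_min[1], tab$range_max[1]), range(d$value))
})

test_that("perfect duplicates give SEM 0 and ICC 1 across the table", {
  agg <- data.frame(subject_id = rep(sprintf("S%d", 1:5), each = 2),
                    observer_id = rep(c("obs1", "obs2"), 5),
                    measure = "triceps",
                    value = rep(c(20, 24, 28, 18, 30), each = 2),
                    stringsAsFactors = FALSE)
  tab <- reliability_table(agg, measures = "triceps")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$sem, 0)
  expect_equal(tab$icc, 1)
  expect_equal(tab$band, "good")
})

test_that("the baseline summary computes the Table-1-style statistics", {
  subjects <- data.frame(
    subject_id = c("S1", "S2"), age = c(28, 32),
    gestational_age_weeks = c(12, 16),
    bmi = c(27.0, 31.0), parity = c(0, 2),
    smoker = c(FALSE, TRUE), ethnicity = c("Caucasian", "Caucasian")
  )
  s <- summarize_cohort(subjects)
  age <- s[s$statistic == "mean_sd", ]
  expect_equal(age$est1, 30.0)
  expect_equal(age$est2, sd(c(28, 32)), tolerance = 1e-12)
  expect_match(age$display, "30.0 \\(2.8\\)")
  ow <- s[grepl("25.0-29.9", s$characteristic), ]
  expect_equal(ow$est1, 1)
  expect_equal(ow$est2, 50)
})

test_that("a cohort of 27 overweight and 22 obese women splits 55.1/44.9", {
  subjects <- data.frame(
    subject_id = sprintf("S%d", 1:49),
    age = rep(30, 49),
    bmi = c(rep(27, 27), rep(32, 22))
  )
  s <- summarize_cohort(subjects)
  expect_equal(s[grepl("25.0-29.9", s$characteristic), "est2"], 100 * 27 / 49,
               tolerance = 1e-12)
  expect_equal(round(s[grepl("25.0-29.9", s$characteristic), "est2"], 1), 55.1)
  expect_equal(round(s[grepl(">= 30.0", s$characteristic), "est2"], 1), 44.9)
})

test_that("a single subject reports SD as not available", {
  s <- summarize_cohort(data.frame(subject_id = "S1", age = 30, bmi = 28))
  expect_match(s$display[s$statistic == "mean_sd"], "not available")
})
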