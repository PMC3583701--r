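# Brute-force variance-components oracle: explicit loops over the
# definitional sums of squares, kept independent of the package's
# vectorised implementation.
oracle_oneway <- function(subject_id, value) {
  subjects <- unique(subject_id)
  n <- length(subjects)
  k <- length(value) / n
  grand <- sum(value) / length(value)
  ss_between <- 0
  ss_within <- 0
  for (s in subjects) {
    v <- value[subject_id == s]
    m <- sum(v) / length(v)
    ss_between <- ss_between + k * (m - grand)^2
    for (y in v) ss_within <- ss_within + (y - m)^2
  }
  ms_between <- ss_between / (n - 1)
  ms_within <- ss_within / (n * (k - 1))
  list(
    ms_between = ms_between,
    ms_within = ms_within,
    icc = (ms_between - ms_within) / (ms_between + (k - 1) * ms_within),
    sem = sqrt(ms_within)
  )
}

# random paired (k observers per subject) measure set
random_paired_set <- function(n, k = 2, mu = 20, sd_subject = 3, sd_error = 2) {
  subj <- rep(sprintf("S%02d", seq_len(n)), each = k)
  data.frame(
    subject_id = subj,
    observer_id = rep(sprintf("obs%d", seq_len(k)), times = n),
    value = rep(stats::rnorm(n, mu, sd_subject), each = k) +
      stats::rnorm(n * k, 0, sd_error),
    stringsAsFactors = FALSE
  )
}

# fixed 6-subject x 2-observer table used across reliability tests
fixed_paired_table <- function() {
  data.frame(
    subject_id = rep(c("A", "B", "C", "D", "E", "F"), each = 2),
    observer_id = rep(c("obs1", "obs2"), times = 6),
    value = c(12.1, 13.0, 18.4, 17.2, 25.3, 24.1,
              9.8, 11.5, 30.2, 28.8, 21.0, 21.6),
    stringsAsFactors = FALSE
  )
}

# minimal conformant raw-readings session for one subject x observer
make_session <- function(subject = "S1", observer = "obs1") {
  data.frame(
    subject_id = subject, observer_id = observer, visit = "entry",
    measure = rep(c("arm_circumference", "biceps", "triceps", "subscapular"),
                  each = 2),
    replicate = rep(1:2, times = 4),
    value = c(34.5, 34.7, 13.1, 13.3, 24.0, 24.4, 25.2, 25.6),
    unit = rep(c("cm", "mm", "mm", "mm"), each = 2),
    stringsAsFactors = FALSE
  )
}
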