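make_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

base_rows <- function() {
  data.frame(
    admission_id = c("A1", "A2", "A3"),
    patient_id = c("P1", "P1", "P2"),
    admission_date = c("2018-01-01", "2018-02-01", "2018-03-05"),
    discharge_date = c("2018-01-04", "2018-02-01", "2018-03-10"),
    total_charge = c(30000, 8000, 52000),
    discharge_status = c("Improved", "Complete recovery", "Dead"),
    department = c("surgery", "surgery", "surgery"),
    stringsAsFactors = FALSE)
}

test_that("registry reading parses dates, recomputes LOS, and rejects bad rows", {
  co <- read_records(make_csv(base_rows()))
  expect_equal(nrow(co), 3)
  expect_equal(co$los, c(3, 1, 5))          # same-day discharge counts as 1 day
  expect_s3_class(co, "los_cohort")
  # discharge before admission is rejected with a reason
  bad <- base_rows()
  bad$discharge_date[2] <- "2017-12-25"
  co2 <- read_records(make_csv(bad))
  expect_equal(nrow(co2), 2)
  rej <- attr(co2, "rejected")
  expect_equal(nrow(rej), 1)
  expect_match(rej$reason, "before")
  # unparseable dates are rejected, not guessed
  bad2 <- base_rows()
  bad2$admission_date[1] <- "not-a-date"
  co3 <- read_records(make_csv(bad2))
  expect_equal(nrow(co3), 2)
  expect_match(attr(co3, "rejected")$reason, "unparseable")
  # missing required columns produce a schema error naming them
  expect_error(read_records(make_csv(base_rows()[, -3])), "admission_date")
})

test_that("column maps, d/m/Y dates, and stored-LOS validation work", {
  rows <- base_rows()
  names(rows)[1] <- "AdmNo"
  co <- read_records(make_csv(rows), column_map = c(admission_id = "AdmNo"))
  expect_equal(co$admission_id, c("A1", "A2", "A3"))
  expect_error(read_records(make_csv(rows), column_map = c(admission_id = "Nope")),
               "not found")
  dmy <- base_rows()
  dmy$admission_date <- c("13/11/2017", "01/02/2018", "05/03/2018")
  dmy$discharge_date <- c("16/11/2017", "01/02/2018", "10/03/2018")
  cod <- read_records(make_csv(dmy), dmy = TRUE)
  expect_equal(cod$los, c(3, 1, 5))
  expect_equal(cod$admission_date[1], as.Date("2017-11-13"))
  # a stored LOS column disagreeing with the dates is reported, dates win
  withlos <- base_rows()
  withlos$los <- c(3, 9, 5)
  expect_message(cow <- read_records(make_csv(withlos)), "disagree")
  expect_equal(cow$los, c(3, 1, 5))
  expect_equal(attr(cow, "los_mismatch"), 2L)
})

test_that("cohorts round-trip through CSV exactly", {
  sim <- make_fixture("rehab", scale = 0.3, seed = 231)
  path <- tempfile(fileext = ".csv")
  write_records(sim$cohort, path)
  back <- read_records(path)
  attr(back, "rejected") <- NULL
  attr(back, "los_mismatch") <- NULL
  expect_equal(as.data.frame(back), as.data.frame(sim$cohort))
})

test_that("aggregation levels conserve LOS-days and collapse patients", {
  co <- read_records(make_csv(base_rows()))
  adm <- per_admission_sample(co, "surgery")
  pat <- per_patient_sample(co, "surgery")
  expect_equal(sort(adm$values), c(1, 3, 5))
  expect_equal(sort(pat$values), c(4, 5))   # P1: 3 + 1 summed
  expect_equal(sum(adm$values), sum(pat$values))
  expect_lte(length(pat), length(adm))
  expect_error(per_admission_sample(co, "icu"), "absent")
  # all-singleton cohort: the two levels coincide
  single <- base_rows()
  single$patient_id <- c("P1", "P2", "P3")
  cos <- read_records(make_csv(single))
  expect_equal(sort(per_patient_sample(cos, "surgery")$values),
               sort(per_admission_sample(cos, "surgery")$values))
})

test_that("discharge statuses classify by exact case-normalized match", {
  expect_equal(classify_status(c("Delivered", "Dead", "Transferred")),
               c("positive", "negative", "unknown"))
  expect_equal(classify_status(c(" improved ", "D/C WITH MOTHER", "d/c separately")),
               c("positive", "positive", "negative"))
  expect_equal(classify_status("Not improved"), "negative")
})

test_that("descriptive statistics use the documented conventions", {
  st <- descriptive_stats(c(1, 2, 3))
  expect_equal(st$mean, 2)
  expect_equal(st$median, 2)
  expect_equal(st$variance, 2 / 3)          # population denominator n
  expect_equal(st$dispersion, 1 / 3)
  expect_equal(st$max, 3)
  expect_equal(descriptive_stats(c(1, 2, 3), variance = "sample")$variance, 1)
  # Pearson vs excess kurtosis differ by exactly 3
  set.seed(241)
  x <- rpois(500, 6) + 1
  expect_equal(descriptive_stats(x)$kurtosis,
               descriptive_stats(x, kurtosis = "excess")$kurtosis + 3)
  expect_warning(stc <- descriptive_stats(rep(4, 10)), "constant")
  expect_equal(stc$variance, 0)
  expect_true(is.na(stc$skewness))
})

test_that("spike frequencies count exact values with neighbor context", {
  sp <- spike_frequency(c(19, 20, 20, 21), 20)
  expect_equal(sp$count, 2)
  expect_equal(sp$fraction, 0.5)
  expect_equal(unname(sp$neighbors), c(1, 1))
  expect_equal(spike_frequency(c(1, 2, 3), 20)$count, 0)
  expect_equal(spike_frequency(c(1, 2, 3), 20)$fraction, 0)
})
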