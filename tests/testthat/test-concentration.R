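test_that("Gini matches hand values and the pairwise-difference oracle", {
  expect_equal(gini(rep(7, 25)), 0)
  expect_equal(gini(c(1, 3)), 0.25)
  set.seed(171)
  for (i in 1:5) {
    x <- sample(0:50, sample(10:200, 1), replace = TRUE)
    if (sum(x) == 0) x[1] <- 1
    expect_equal(gini(x), oracle_gini(x), tolerance = 1e-12)
    expect_equal(gini(3.7 * x), gini(x), tolerance = 1e-12)   # scale invariance
  }
  expect_equal(gini(c(1, 3), unbiased = TRUE), 0.5)
  expect_error(gini(rep(0, 5)), "undefined")
  expect_error(gini(c(-1, 2)), "non-negative")
})

test_that("Gini increases as the Beta-Geometric tail gets heavier at fixed-ish mean", {
  alphas <- c(5, 3, 2.2, 1.5)
  g <- vapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    b <- if (a > 1) 4 * (a - 1) - a + 1 else 3   # mean (a+b-1)/(a-1) = 4
    gini(bg_sample(1e5, bg_params(a, b), seed = 180 + i))
  }, numeric(1))
  expect_true(all(diff(g) > 0))
})

test_that("bootstrap Gini is seeded, contains the point estimate, and scales like 1/sqrt(n)", {
  set.seed(191)
  x <- rgeom(4000, 0.2) + 1
  b1 <- gini_bootstrap(x, n_boot = 400, seed = 192)
  b2 <- gini_bootstrap(x, n_boot = 400, seed = 192)
  expect_identical(b1$se, b2$se)
  expect_equal(b1$gini, gini(x))
  expect_true(b1$ci[1] <= b1$gini && b1$gini <= b1$ci[2])
  b_small <- gini_bootstrap(x[1:1000], n_boot = 400, seed = 193)
  expect_gt(b_small$se / b1$se, 1.6)
  expect_lt(b_small$se / b1$se, 2.4)
})

test_that("Lorenz curves have exact endpoints, reflect, and integrate to the Gini", {
  lc <- lorenz(c(1, 1, 8), reversed = TRUE)
  expect_equal(lc$population_fraction[1], 0)
  expect_equal(lc$value_fraction[1], 0)
  expect_equal(tail(lc$population_fraction, 1), 1)
  expect_equal(tail(lc$value_fraction, 1), 1)
  expect_equal(lc$value_fraction[lc$population_fraction == 1 / 3], 0.8)
  set.seed(201)
  x <- rpois(500, 5) + 1
  std <- lorenz(x)
  rev <- lorenz(x, reversed = TRUE)
  # point reflection through (1/2, 1/2)
  expect_equal(rev$value_fraction, rev(1 - std$value_fraction), tolerance = 1e-12)
  # trapezoid area under the standard curve recovers the Gini to 1/n
  n <- length(x)
  area <- sum((std$value_fraction[-1] + std$value_fraction[-(n + 1)]) / 2) / n
  expect_equal(1 - 2 * area, gini(x), tolerance = 1 / n)
})

test_that("concentration shares match hand values and are monotone", {
  expect_equal(concentration_share(c(1, 1, 8), 0.5), 1 / 3)
  expect_equal(concentration_share(c(1, 1, 8), 1.0), 1.0)
  set.seed(211)
  x <- bg_sample(5000, bg_params(2, 6))
  shares <- vapply(c(0.2, 0.4, 0.6, 0.8, 1), function(s)
    concentration_share(x, s), numeric(1))
  expect_true(all(diff(shares) > 0))
  expect_error(concentration_share(x, 1.2), "value_share")
})

test_that("elbow detection finds piecewise-linear breakpoints and flags straight lines", {
  x <- 1:40
  y <- ifelse(x <= 14, 100 - 5 * x, 30 - 0.2 * (x - 14))
  eb <- find_elbow(x, y)
  expect_true(eb$found)
  expect_equal(eb$x, 14)
  line <- find_elbow(1:30, 2 + 3 * (1:30))
  expect_false(line$found)
  expect_error(find_elbow(1:2, 1:2), "3 points")
  # two breakpoints: recurse on the remainder past the first elbow
  y2 <- ifelse(x <= 14, 200 - 10 * x, ifelse(x <= 30, 60 - 1.2 * (x - 14), 40.8 - 0.05 * (x - 30)))
  e1 <- find_elbow(x, y2)
  expect_equal(e1$x, 14)
  rest <- x >= 14
  e2 <- find_elbow(x[rest], y2[rest])
  expect_equal(e2$x, 30)
})

test_that("charge-per-day curves aggregate admissions by exact LOS", {
  rec <- data.frame(
    admission_id = as.character(1:3), patient_id = as.character(1:3),
    admission_date = as.Date("2018-01-01") + 0:2,
    discharge_date = as.Date("2018-01-03") + c(0, 0, 2),
    los = c(2, 2, 4), total_charge = c(200, 400, 1000),
    discharge_status = c("Improved", "Dead", "Improved"),
    department = "surgery", stringsAsFactors = FALSE)
  cv <- charge_per_day_curve(rec, "surgery")
  expect_equal(cv$mean_daily_charge[cv$los == 2], 150)    # (100 + 200) / 2
  expect_equal(cv$n[cv$los == 2], 2)
  expect_equal(nrow(charge_per_day_curve(rec[3, ], "surgery")), 1)
  pos <- charge_per_day_curve(rec, "surgery", status_filter = "positive")
  expect_equal(pos$n, c(1, 1))
  expect_error(charge_per_day_curve(rec, "icu"), "absent")
})

test_that("piecewise correlations hit exact cases and flag degenerate ranges", {
  cv <- structure(data.frame(los = 1:20,
                             mean_daily_charge = c(100 - 3 * (1:10), rep(50, 10)),
                             n = rep(5, 20)),
                  class = c("charge_curve", "data.frame"))
  pc <- piecewise_correlation(cv, list(c(1, 10), c(11, 20)))
  expect_equal(pc$r[1], -1)
  expect_true(is.na(pc$r[2]))              # constant segment: undefined
  expect_error(piecewise_correlation(cv, list(c(1, 12), c(10, 20))), "disjoint")
  # weighted mode agrees with unweighted under equal counts
  pw <- piecewise_correlation(cv, list(c(1, 10)), weighted = TRUE)
  expect_equal(pw$r[1], -1)
})

test_that("bootstrap piecewise correlation is seeded and carries intervals", {
  sim <- make_fixture("surgery", scale = 0.02, seed = 221)
  cv <- charge_per_day_curve(sim$cohort, "surgery")
  pc1 <- piecewise_correlation(cv, list(c(1, 14)), records = sim$cohort,
                               department = "surgery", n_boot = 100, seed = 222)
  pc2 <- piecewise_correlation(cv, list(c(1, 14)), records = sim$cohort,
                               department = "surgery", n_boot = 100, seed = 222)
  expect_identical(pc1$se, pc2$se)
  expect_true(pc1$ci_low[1] <= pc1$ci_high[1])
  expect_gt(pc1$se[1], 0)
  expect_lt(pc1$r[1], -0.8)
})
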