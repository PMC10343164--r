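test_that("PMF matches closed forms, the log-gamma oracle, and shift translation", {
  expect_equal(bg_pmf(1, bg_params(2, 2)), 0.5)          # alpha / (alpha + beta)
  expect_equal(bg_pmf(1, bg_params(2, 3)), 0.4)
  # alpha = beta = 1 telescopes to 1 / (x (x + 1))
  expect_equal(bg_pmf(1:50, bg_params(1, 1)), 1 / ((1:50) * (2:51)), tolerance = 1e-12)
  # direct log-gamma oracle across a parameter grid
  for (ab in list(c(0.7, 2), c(1.5, 3), c(7.03, 38.6), c(37.3, 387.4))) {
    x <- c(1:20, 100, 1000)
    expect_equal(bg_pmf(x, bg_params(ab[1], ab[2])),
                 oracle_bg_pmf(x, ab[1], ab[2]), tolerance = 1e-12)
  }
  # shift is a pure translation
  p0 <- bg_params(3.3, 11, shift = 0)
  p20 <- bg_params(3.3, 11, shift = 20)
  expect_equal(bg_pmf(21:40, p20), bg_pmf(1:20, p0))
  # domain and parameter errors
  expect_error(bg_pmf(0, p0), "support")
  expect_error(bg_pmf(20, p20), "support")
  expect_error(bg_params(-1, 2), "alpha")
  expect_error(bg_params(2, 0), "beta")
})

test_that("survival and CDF agree with partial PMF sums and telescope exactly", {
  expect_equal(bg_sf(3, bg_params(1, 1)), 0.25)
  expect_equal(bg_sf(0, bg_params(4.2, 9)), 1)
  expect_equal(bg_sf(1, bg_params(2, 3)), 0.6)
  expect_equal(bg_cdf(1, bg_params(2, 2)), 0.5)
  expect_equal(bg_cdf(2, bg_params(1, 1)), 2 / 3)
  for (ab in list(c(0.8, 1.5), c(2, 2), c(7.03, 38.6))) {
    prm <- bg_params(ab[1], ab[2])
    x <- c(1:30, 100, 5000, 10000)
    expect_equal(bg_cdf(x, prm),
                 vapply(x, function(xi) sum(bg_pmf(seq_len(xi), prm)), numeric(1)),
                 tolerance = 1e-12)
    expect_true(all(diff(bg_sf(0:100, prm)) <= 0))
  }
  # normalization: mass accumulates to 1 for a high cutoff (the survival
  # decays like x^-alpha, so the cutoff needed grows as alpha shrinks)
  expect_gte(sum(bg_pmf(1:1e6, bg_params(2, 5))), 1 - 1e-9)
  expect_lt(bg_sf(1e6, bg_params(2, 5)), 1e-9)
  expect_gte(sum(bg_pmf(1:1e6, bg_params(1.2, 3))), 1 - 1e-6)
})

test_that("PMF converges to the shifted geometric in the degenerate-Beta limit", {
  c0 <- 1e4
  prm <- bg_params(c0 * 2, c0 * 6)
  p <- 2 / (2 + 6)
  x <- 1:40
  expect_equal(bg_pmf(x, prm), p * (1 - p)^(x - 1), tolerance = 1e-3)
})

test_that("mean and variance match summation oracles and signal divergence", {
  expect_equal(bg_mean(bg_params(3, 6)), 4)
  expect_equal(bg_mean(bg_params(3, 6)), oracle_bg_moment(3, 6), tolerance = 1e-6)
  expect_equal(bg_mean(bg_params(37.3032, 387.4253)), 11.67193, tolerance = 1e-5)
  expect_equal(bg_mean(bg_params(37.3032, 387.4253)),
               oracle_bg_moment(37.3032, 387.4253), tolerance = 1e-6)
  expect_equal(bg_mean(bg_params(3, 6, shift = 20)), 24)
  expect_identical(bg_mean(bg_params(1, 3)), Inf)
  expect_identical(bg_variance(bg_params(1.5, 3)), Inf)
  v <- bg_variance(bg_params(3, 6))
  expect_equal(v, oracle_bg_moment(3, 6, pow = 2) - oracle_bg_moment(3, 6)^2,
               tolerance = 1e-4)
  # degenerate-Beta limit: geometric variance (1 - p) / p^2 with p = 1 / (1 + k)
  k <- 3
  expect_equal(bg_variance(bg_params(1e5, 1e5 * k)),
               (1 - 1 / (1 + k)) * (1 + k)^2, tolerance = 1e-3)
})

test_that("sampler is seed-deterministic and consistent with the closed forms", {
  prm <- bg_params(7.03, 38.6)
  s1 <- bg_sample(1e5, prm, seed = 11)
  s2 <- bg_sample(1e5, prm, seed = 11)
  expect_identical(s1, s2)
  p1 <- 7.03 / (7.03 + 38.6)
  se <- sqrt(p1 * (1 - p1) / 1e5)
  expect_lt(abs(mean(s1 == 1) - p1), 3 * se)
  # E[X] = (alpha + beta - 1)/(alpha - 1) = 4; pooled over seeds because the
  # third moment is infinite at alpha = 3 and single-sample means are skewed
  m3 <- vapply(1:10, function(s) mean(bg_sample(1e5, bg_params(3, 6), seed = s)),
               numeric(1))
  se_mean <- sqrt(bg_variance(bg_params(3, 6)) / 1e6)
  expect_lt(abs(mean(m3) - 4), 3 * se_mean)
  expect_error(bg_sample(0, prm), "positive integer")
})

test_that("empirical CDF of a large draw stays inside the DKW band", {
  prm <- bg_params(2.5, 7)
  n <- 1e6
  x <- bg_sample(n, prm, seed = 21)
  eps <- sqrt(log(2 / 0.01) / (2 * n))     # 99% band
  grid <- 0:max(x)
  emp <- findInterval(grid, sort(x)) / n
  expect_lt(max(abs(emp - bg_cdf(grid, prm))), eps)
})

test_that("truncated-Gaussian fit recovers parameters and underweights heavy tails", {
  set.seed(31)
  x <- rtruncgauss(1e4, 10, 3, lower = 1)
  ft <- fit_truncated_gaussian(x)
  expect_lt(abs(ft$mu - 10) / 10, 0.05)
  expect_lt(abs(ft$sigma - 3) / 3, 0.05)
  expect_error(fit_truncated_gaussian(rep(5, 50)), "constant")
  # heavy-tailed sample: fitted survival at the empirical 99th percentile
  # falls below the empirical tail frequency
  h <- bg_sample(2e4, bg_params(1.3, 3), seed = 32)
  fh <- fit_truncated_gaussian(h)
  q99 <- unname(quantile(h, 0.99, type = 1))
  expect_lt(tg_sf(q99, fh), mean(h > q99))
})

test_that("truncated Poisson renormalizes, recovers its rate, and reduces to the mean", {
  prm <- tp_params(8, 1L, 19L)
  expect_equal(sum(tp_pmf(1:19, prm)), 1, tolerance = 1e-12)
  expect_equal(sum(tp_pmf(1:19, tp_params(0.3, 1L, 19L))), 1, tolerance = 1e-12)
  expect_equal(tp_pmf(25, prm), 0)
  set.seed(41)
  x <- rpois(1e4, 5)
  expect_equal(fit_trunc_poisson(x, lower = 0L, upper = Inf)$rate, mean(x))
  xs <- tp_sample(1e4, prm, seed = 42)
  expect_true(all(xs >= 1 & xs <= 19))
  ft <- fit_trunc_poisson(xs, 1L, 19L)
  expect_lt(abs(ft$rate - 8) / 8, 0.05)
  expect_equal(ft$rate, oracle_tp_mle(xs, 1, 19), tolerance = 0.01)
  expect_error(fit_trunc_poisson(c(25, 30), 1L, 19L), "no observations")
})
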