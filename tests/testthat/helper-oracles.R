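# Independent brute-force oracles, kept deliberately naive: each recomputes a
# quantity by direct enumeration so the fast implementation is checked against
# a route that shares no code with it.

# P(X = x) by direct log-gamma evaluation of the Beta-function ratio
oracle_bg_pmf <- function(x, alpha, beta) {
  exp(lgamma(alpha + 1) + lgamma(beta + x - 1) - lgamma(alpha + beta + x) -
        (lgamma(alpha) + lgamma(beta) - lgamma(alpha + beta)))
}

# survival by partial PMF sums
oracle_bg_sf <- function(x, alpha, beta) {
  1 - sum(oracle_bg_pmf(seq_len(x), alpha, beta))
}

# mean/second moment by truncated summation to tail tolerance
oracle_bg_moment <- function(alpha, beta, pow = 1, tol = 1e-10, xmax = 1e7) {
  x <- 1
  total <- 0
  block <- 1e5
  while (x < xmax) {
    xs <- x:min(x + block - 1, xmax)
    total <- total + sum(xs^pow * oracle_bg_pmf(xs, alpha, beta))
    if (oracle_bg_sf(min(x + block - 1, xmax), alpha, beta) *
        (x + block)^pow < tol) break
    x <- x + block
  }
  total
}

# two-sample KS D by exhaustive evaluation of both ECDFs on a grid
oracle_ks_d <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(vapply(grid, function(g) abs(mean(a <= g) - mean(b <= g)), numeric(1)))
}

# mean excess by double loop
oracle_mean_excess <- function(x) {
  u <- sort(unique(x))
  u <- u[-length(u)]
  data.frame(threshold = u,
             me = vapply(u, function(a) mean(x[x > a] - a), numeric(1)),
             tail_count = vapply(u, function(a) sum(x > a), numeric(1)))
}

# Gini by the quadratic mean-absolute-difference formula
oracle_gini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# truncated-Poisson MLE by grid search over the rate
oracle_tp_mle <- function(x, lower, upper, grid = seq(0.5, 30, by = 0.005)) {
  ll <- vapply(grid, function(lam) {
    z <- ppois(upper, lam) - ppois(lower - 1, lam)
    sum(dpois(x, lam, log = TRUE)) - length(x) * log(z)
  }, numeric(1))
  grid[which.max(ll)]
}

# Theil-Sen slope (median of pairwise slopes); sign test for monotonicity
theil_sen_slope <- function(x, y) {
  n <- length(x)
  if (n > 400) {               # subsample pairs for big curves
    idx <- round(seq(1, n, length.out = 400))
    x <- x[idx]; y <- y[idx]; n <- 400
  }
  dx <- outer(x, x, "-"); dy <- outer(y, y, "-")
  keep <- upper.tri(dx) & dx != 0
  stats::median(dy[keep] / dx[keep])
}

# draw from a Gaussian truncated below at `lower` by inverse CDF
rtruncgauss <- function(n, mu, sigma, lower = 1) {
  qnorm(runif(n, pnorm(lower, mu, sigma), 1), mu, sigma)
}

# equal-probability-cell means of a Pareto(shape) on [1, Inf): an exact
# quadrature of the analytic law, usable as a finite population
pareto_cell_means <- function(shape, n_cells) {
  q <- seq(0, 1, length.out = n_cells + 1)
  tails <- (1 - q)^(1 - 1 / shape)
  (shape / (shape - 1)) * (tails[-(n_cells + 1)] - tails[-1]) * n_cells
}
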