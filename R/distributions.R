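#' Shifted Beta-Geometric parameter set
#'
#' Defines the law of a discharge process in which each admitted patient has a
#' constant daily discharge probability `p`, with `p` itself drawn from a
#' Beta(`alpha`, `beta`) distribution across patients. The number of days
#' until discharge then follows a Beta-Geometric distribution on
#' `{shift + 1, shift + 2, ...}`; with `shift = 0` the support is
#' `{1, 2, 3, ...}`, matching length-of-stay data whose minimum is one day.
#'
#' @param alpha positive shape of the Beta law of the daily discharge
#'   probability. Smaller `alpha` gives heavier tails; moments of order `k`
#'   exist iff `alpha > k`.
#' @param beta positive shape of the Beta law.
#' @param shift non-negative integer translation of the support; used to model
#'   tails above a policy threshold (values `> shift`).
#' @return an object of class `"bg_params"`.
#' @examples
#' p <- bg_params(7.03, 38.6)
#' bg_pmf(1:5, p)
#' @export
bg_params <- function(alpha, beta, shift = 0L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("'alpha' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    stop("'beta' must be a single positive finite number", call. = FALSE)
  if (!is.numeric(shift) || length(shift) != 1L || shift < 0 || shift != round(shift))
    stop("'shift' must be a single non-negative integer", call. = FALSE)
  structure(list(alpha = as.numeric(alpha), beta = as.numeric(beta),
                 shift = as.integer(shift)),
            class = "bg_params")
}

#' @export
print.bg_params <- function(x, ...) {
  cat(sprintf("Beta-Geometric(alpha = %g, beta = %g, shift = %d)\n",
              x$alpha, x$beta, x$shift))
  m <- bg_mean(x)
  cat(sprintf("  mean: %s   variance: %s\n",
              if (is.finite(m)) format(m) else "infinite",
              if (is.finite(bg_variance(x))) format(bg_variance(x)) else "infinite"))
  invisible(x)
}

check_bg <- function(params) {
  if (!inherits(params, "bg_params"))
    stop("'params' must be a 'bg_params' object (see bg_params())", call. = FALSE)
  params
}

#' Beta-Geometric probability mass function
#'
#' `P(X = x) = B(alpha + 1, beta + x - shift - 1) / B(alpha, beta)` for
#' `x` in `{shift + 1, shift + 2, ...}`. All Beta-function ratios are
#' evaluated as differences of log-gamma sums ([lbeta()]): the second Beta
#' argument grows with `x` and raw Gamma ratios overflow long before the
#' sample maxima seen in practice.
#'
#' @param x integer vector of support points (`>= shift + 1`).
#' @param params a [bg_params()] object.
#' @param log if `TRUE`, return log-probabilities.
#' @return numeric vector of (log-)probabilities.
#' @export
bg_pmf <- function(x, params, log = FALSE) {
  check_bg(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != round(x)))
    stop("'x' must be a vector of finite integers", call. = FALSE)
  z <- x - params$shift
  if (any(z < 1))
    stop("'x' outside the support {shift+1, shift+2, ...}", call. = FALSE)
  lp <- lbeta(params$alpha + 1, params$beta + z - 1) - lbeta(params$alpha, params$beta)
  if (log) lp else exp(lp)
}

#' Beta-Geometric survival function
#'
#' `P(X > x) = B(alpha, beta + x - shift) / B(alpha, beta)`, valid for
#' `x >= shift` (and equal to 1 at `x = shift`). This is the telescoped form
#' of the complementary cumulative PMF sum.
#'
#' @inheritParams bg_pmf
#' @param x integer vector, `>= shift`.
#' @return `P(X > x)` for each element of `x`.
#' @export
bg_sf <- function(x, params) {
  check_bg(params)
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != round(x)))
    stop("'x' must be a vector of finite integers", call. = FALSE)
  z <- x - params$shift
  if (any(z < 0))
    stop("'x' must be >= shift", call. = FALSE)
  exp(lbeta(params$alpha, params$beta + z) - lbeta(params$alpha, params$beta))
}

#' Beta-Geometric cumulative distribution function
#'
#' Right-continuous step CDF on the integers: `P(X <= x) = 1 - bg_sf(x)`.
#'
#' @inheritParams bg_sf
#' @export
bg_cdf <- function(x, params) {
  1 - bg_sf(x, params)
}

#' Sample from a shifted Beta-Geometric distribution
#'
#' Two-stage compound draw: for each of the `n` variates a discharge
#' probability `p` is drawn from Beta(`alpha`, `beta`), then the day of first
#' discharge is a geometric count of trials (inverse-CDF in double precision,
#' so very small `p` cannot overflow integer storage), plus `shift`.
#'
#' @param n number of draws.
#' @param params a [bg_params()] object.
#' @param seed optional integer; when given, the draw is made under this seed
#'   and the caller's RNG state is restored afterwards.
#' @return integer-valued numeric vector of length `n`.
#' @export
bg_sample <- function(n, params, seed = NULL) {
  check_bg(params)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a single positive integer", call. = FALSE)
  with_seed(seed, {
    p <- stats::rbeta(n, params$alpha, params$beta)
    p <- pmin(pmax(p, .Machine$double.xmin), 1)
    # trials-to-first-success: 1 + floor(log(U)/log(1-p)), robust for tiny p
    g <- 1 + floor(log(stats::runif(n)) / log1p(-p))
    g[p == 1] <- 1
    g + params$shift
  })
}

#' Mean of the Beta-Geometric distribution
#'
#' Closed form `(alpha + beta - 1) / (alpha - 1) + shift` when `alpha > 1`;
#' the mean does not exist for `alpha <= 1` and `Inf` is returned as an
#' explicit signal (never an error), so that tail diagnostics can branch on
#' moment existence.
#'
#' @param params a [bg_params()] object.
#' @return the mean, or `Inf` when the first moment diverges.
#' @export
bg_mean <- function(params) {
  check_bg(params)
  if (params$alpha <= 1) return(Inf)
  (params$alpha + params$beta - 1) / (params$alpha - 1) + params$shift
}

#' Variance of the Beta-Geometric distribution
#'
#' Finite iff `alpha > 2`. Uses `E[X^2] = 2 E[p^-2] - E[p^-1]` for the
#' unshifted law, with the negative moments of the Beta law as Beta-function
#' ratios: `E[p^-1] = (a+b-1)/(a-1)`, `E[p^-2] = (a+b-1)(a+b-2)/((a-1)(a-2))`.
#' The shift does not affect the variance. Returns `Inf` when `alpha <= 2`.
#'
#' @inheritParams bg_mean
#' @export
bg_variance <- function(params) {
  check_bg(params)
  a <- params$alpha; b <- params$beta
  if (a <= 2) return(Inf)
  m1 <- (a + b - 1) / (a - 1)
  ep2 <- (a + b - 1) * (a + b - 2) / ((a - 1) * (a - 2))
  m2 <- 2 * ep2 - m1
  m2 - m1^2
}

# ---- truncated Gaussian baseline --------------------------------------------

#' Truncated Gaussian parameter set
#'
#' Gaussian truncated below at `lower` (1 day by convention: LOS has minimum
#' one day and integer values are treated as continuous for this baseline
#' comparator).
#'
#' @param mu location of the untruncated Gaussian.
#' @param sigma positive scale.
#' @param lower truncation bound in days.
#' @return an object of class `"tg_params"`.
#' @export
tg_params <- function(mu, sigma, lower = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu))
    stop("'mu' must be a single finite number", call. = FALSE)
  structure(list(mu = as.numeric(mu), sigma = as.numeric(sigma),
                 lower = as.numeric(lower)),
            class = "tg_params")
}

#' Truncated Gaussian density and survival
#'
#' @param x numeric vector (`>= lower`; density is 0 below the bound).
#' @param params a [tg_params()] object.
#' @param log return the log density.
#' @return `tg_density`: the density; `tg_sf`: `P(X > x)`.
#' @export
tg_density <- function(x, params, log = FALSE) {
  stopifnot(inherits(params, "tg_params"))
  lz <- stats::pnorm(params$lower, params$mu, params$sigma,
                     lower.tail = FALSE, log.p = TRUE)
  ld <- stats::dnorm(x, params$mu, params$sigma, log = TRUE) - lz
  ld[x < params$lower] <- -Inf
  if (log) ld else exp(ld)
}

#' @rdname tg_density
#' @export
tg_sf <- function(x, params) {
  stopifnot(inherits(params, "tg_params"))
  s <- stats::pnorm(pmax(x, params$lower), params$mu, params$sigma, lower.tail = FALSE) /
    stats::pnorm(params$lower, params$mu, params$sigma, lower.tail = FALSE)
  pmin(s, 1)
}

#' Maximum-likelihood fit of a below-truncated Gaussian
#'
#' Numerically maximizes the truncated-Gaussian likelihood, treating the
#' integer durations as continuous. Serves as the thin-tailed visual baseline
#' against which the heavy right tail of length-of-stay data stands out.
#'
#' @param sample numeric durations (all `>= lower`), or an `los_sample`.
#' @param lower truncation bound (1 day).
#' @return a [tg_params()] object with attributes `loglik` and `converged`.
#' @export
fit_truncated_gaussian <- function(sample, lower = 1) {
  x <- as_los_values(sample)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate (constant) sample: truncated-Gaussian fit is undefined",
         call. = FALSE)
  nll <- function(par) {
    mu <- par[1]; sig <- exp(par[2])
    -sum(stats::dnorm(x, mu, sig, log = TRUE)) +
      length(x) * stats::pnorm(lower, mu, sig, lower.tail = FALSE, log.p = TRUE)
  }
  op <- stats::optim(c(mean(x), log(stats::sd(x))), nll, method = "BFGS",
                     control = list(maxit = 500))
  out <- tg_params(op$par[1], exp(op$par[2]), lower)
  attr(out, "loglik") <- -op$value
  attr(out, "converged") <- op$convergence == 0L
  out
}

# ---- truncated Poisson body -------------------------------------------------

#' Truncated Poisson parameter set
#'
#' A Poisson law renormalized to the integer support `[lower, upper]`; the
#' short-stay body of a policy-censored ward is modeled this way on
#' `1 .. threshold - 1`.
#'
#' @param rate positive Poisson rate.
#' @param lower integer lower support bound.
#' @param upper integer upper support bound, or `Inf`.
#' @return an object of class `"tp_params"`.
#' @export
tp_params <- function(rate, lower = 1L, upper = Inf) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("'rate' must be a single positive number", call. = FALSE)
  if (is.finite(upper) && lower > upper)
    stop("'lower' must not exceed 'upper'", call. = FALSE)
  structure(list(rate = as.numeric(rate), lower = as.integer(lower),
                 upper = as.numeric(upper)),
            class = "tp_params")
}

#' Truncated Poisson PMF
#'
#' @param x integer vector; mass is 0 outside `[lower, upper]`.
#' @param params a [tp_params()] object.
#' @return renormalized probabilities summing to 1 on the support.
#' @export
tp_pmf <- function(x, params) {
  stopifnot(inherits(params, "tp_params"))
  lo <- params$lower; up <- params$upper; lam <- params$rate
  z <- stats::ppois(if (is.finite(up)) up else Inf, lam) - stats::ppois(lo - 1, lam)
  p <- stats::dpois(x, lam) / z
  p[x < lo | x > up] <- 0
  p
}

#' Sample from a truncated Poisson
#'
#' Inverse-CDF draw conditioned on the support window.
#'
#' @param n number of draws.
#' @param params a [tp_params()] object.
#' @param seed optional integer seed (caller RNG state restored).
#' @export
tp_sample <- function(n, params, seed = NULL) {
  stopifnot(inherits(params, "tp_params"))
  lo <- params$lower; up <- params$upper; lam <- params$rate
  plo <- stats::ppois(lo - 1, lam)
  pup <- if (is.finite(up)) stats::ppois(up, lam) else 1
  with_seed(seed, {
    u <- stats::runif(n, plo, pup)
    x <- stats::qpois(u, lam)
    pmin(pmax(x, lo), if (is.finite(up)) up else x)
  })
}

#' Maximum-likelihood fit of a truncated Poisson
#'
#' In the untruncated case (`lower = 0`, `upper = Inf`) the MLE is the sample
#' mean; otherwise the renormalized likelihood is maximized numerically in
#' one dimension.
#'
#' @param sample integer durations, all inside `[lower, upper]`.
#' @param lower,upper integer support bounds of the truncation window.
#' @return a [tp_params()] object with attribute `loglik`.
#' @export
fit_trunc_poisson <- function(sample, lower = 1L, upper = Inf) {
  x <- as_los_values(sample, min_value = lower)
  x <- x[x >= lower & x <= upper]
  if (length(x) == 0) stop("no observations inside [lower, upper]", call. = FALSE)
  if (lower <= 0 && !is.finite(upper)) {
    out <- tp_params(mean(x), lower, upper)
    attr(out, "loglik") <- sum(stats::dpois(x, mean(x), log = TRUE))
    return(out)
  }
  nll <- function(loglam) {
    lam <- exp(loglam)
    lz <- log(stats::ppois(if (is.finite(upper)) upper else Inf, lam) -
                stats::ppois(lower - 1, lam))
    -(sum(stats::dpois(x, lam, log = TRUE)) - length(x) * lz)
  }
  hi <- max(mean(x) * 10, if (is.finite(upper)) upper else 0, 10)
  op <- stats::optimize(nll, interval = log(c(1e-3, hi)))
  out <- tp_params(exp(op$minimum), lower, upper)
  attr(out, "loglik") <- -op$objective
  out
}

# ---- internal RNG scoping ---------------------------------------------------

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  genv <- globalenv()
  if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    old <- get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = genv), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = genv), add = TRUE)
  }
  set.seed(as.integer(seed))
  code
}
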