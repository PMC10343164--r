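#' Beta-Geometric log-likelihood
#'
#' For observations `x_1, ..., x_n` the log-likelihood is
#' `sum_i log B(alpha + 1, beta + x_i - shift - 1) - n log B(alpha, beta)`
#' (the sum over observations of the log PMF). The computation tabulates the
#' sample first, so the cost scales with the number of distinct LOS values,
#' not the sample size.
#'
#' @param sample integer durations (all `> shift`), or an `los_sample`.
#' @param params a [bg_params()] object.
#' @return the log-likelihood on the natural-log scale.
#' @export
loglik_betageometric <- function(sample, params) {
  check_bg(params)
  x <- as_los_values(sample)
  if (any(x <= params$shift))
    stop("sample values must all exceed 'shift'", call. = FALSE)
  tab <- table(x)
  v <- as.numeric(names(tab)) - params$shift
  cnt <- as.numeric(tab)
  sum(cnt * lbeta(params$alpha + 1, params$beta + v - 1)) -
    length(x) * lbeta(params$alpha, params$beta)
}

# Method-of-moments starting point: match P(X=1) = a/(a+b) and the
# closed-form mean (a+b-1)/(a-1). Returns NULL when the moment equations
# have no admissible solution (e.g. heavy tails with huge sample mean).
bg_mom_start <- function(x) {
  p1 <- mean(x == 1)
  m <- mean(x)
  if (p1 <= 0 || p1 >= 1 || m <= 1) return(NULL)
  denom <- 1 - m * p1
  if (denom >= 0) return(NULL)          # needs m * p1 > 1 for a + b > 0
  s <- (1 - m) / denom
  a <- p1 * s
  if (!is.finite(s) || a <= 1 || s - a <= 0) return(NULL)
  c(a, s - a)
}

#' Maximum-likelihood fit of a shifted Beta-Geometric distribution
#'
#' Maximizes [loglik_betageometric()] over `(alpha, beta)` in log-parameter
#' space with a quasi-Newton optimizer and multiple starting points: a
#' method-of-moments start (matching the mass at the support minimum and the
#' sample mean) plus dispersed fallbacks. The likelihood surface is
#' ridge-shaped when `alpha + beta` is large, which is why a single start is
#' not trusted.
#'
#' @param sample integer durations, all `> shift`.
#' @param shift non-negative integer support shift (the fitted law lives on
#'   `{shift + 1, shift + 2, ...}`).
#' @param n_starts number of starting points actually attempted (max 5).
#' @return an object of class `"bg_fit"`: `params` ([bg_params()]), `loglik`,
#'   `n`, `converged`, `n_starts`, `start_used`, and `message` describing any
#'   boundary or convergence problem. Boundary divergence (estimates pinned at
#'   the optimizer box) is reported via `converged = FALSE`, never silently.
#' @export
fit_betageometric <- function(sample, shift = 0L, n_starts = 5L) {
  x0 <- as_los_values(sample)
  if (any(x0 <= shift))
    stop("sample values must all exceed 'shift'", call. = FALSE)
  x <- x0 - shift
  n <- length(x)
  if (n < 10) stop("need at least 10 observations to fit", call. = FALSE)
  if (length(unique(x)) < 2) {
    return(structure(list(params = NULL, loglik = NA_real_, n = n,
                          converged = FALSE, n_starts = 0L, start_used = NULL,
                          message = "degenerate sample: all values equal; the MLE pushes P(X = min) to 1 (boundary)"),
                     class = "bg_fit"))
  }
  tab <- table(x)
  v <- as.numeric(names(tab))
  cnt <- as.numeric(tab)
  # box in log space: outside it log-gamma cancellation degrades the
  # likelihood evaluation itself, and estimates there are boundary cases anyway
  box <- 16
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    if (!is.finite(a) || !is.finite(b)) return(1e300)
    val <- -(sum(cnt * lbeta(a + 1, b + v - 1)) - n * lbeta(a, b))
    if (!is.finite(val)) 1e300 else val
  }
  starts <- list(bg_mom_start(x),
                 c(1, 1), c(0.5, 2), c(5, 20), c(50, 300))
  starts <- Filter(Negate(is.null), starts)
  starts <- starts[seq_len(min(length(starts), n_starts))]
  best <- NULL
  for (i in seq_along(starts)) {
    op <- tryCatch(
      stats::optim(log(starts[[i]]), nll, method = "L-BFGS-B",
                   lower = c(-box, -box), upper = c(box, box),
                   control = list(maxit = 1000, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(op)) next
    if (is.null(best) || op$value < best$op$value)
      best <- list(op = op, start = starts[[i]], index = i)
  }
  if (is.null(best)) stop("all optimizer starts failed", call. = FALSE)
  op <- best$op
  ab <- exp(op$par)
  # honest convergence: optimizer status, gradient norm, and box interior
  gr <- numeric(2)
  h <- 1e-5
  for (j in 1:2) {
    e <- c(0, 0); e[j] <- h
    gr[j] <- (nll(op$par + e) - nll(op$par - e)) / (2 * h)
  }
  grad_ok <- sqrt(sum(gr^2)) < 1e-4 * (1 + abs(op$value))
  at_bound <- any(abs(op$par) > box - 1e-3)
  msg <- NULL
  if (at_bound) msg <- "estimate at parameter-space boundary"
  else if (op$convergence != 0L) msg <- sprintf("optimizer code %d", op$convergence)
  else if (!grad_ok) msg <- "gradient norm above tolerance at reported optimum"
  structure(list(params = bg_params(ab[1], ab[2], shift),
                 loglik = -op$value, n = n,
                 converged = op$convergence == 0L && grad_ok && !at_bound,
                 n_starts = length(starts),
                 start_used = best$start,
                 message = msg),
            class = "bg_fit")
}

#' @export
print.bg_fit <- function(x, ...) {
  cat("Beta-Geometric maximum-likelihood fit\n")
  if (is.null(x$params)) {
    cat("  <no estimate>", if (!is.null(x$message)) paste0(" (", x$message, ")"), "\n")
    return(invisible(x))
  }
  cat(sprintf("  alpha = %.6g, beta = %.6g, shift = %d\n",
              x$params$alpha, x$params$beta, x$params$shift))
  cat(sprintf("  log-likelihood = %.4f   n = %d   converged: %s\n",
              x$loglik, x$n, x$converged))
  if (!is.null(x$message)) cat("  note:", x$message, "\n")
  invisible(x)
}

# ---- threshold-split mixture ------------------------------------------------

#' Threshold-split length-of-stay mixture
#'
#' A three-part model for wards whose stays are administratively cut short at
#' a policy threshold `T`: a truncated-Poisson body on `1 .. T - 1`, an
#' optional point mass exactly at `T` (the policy spike), and a shifted
#' Beta-Geometric tail for the stays the policy did not reach. Component
#' supports are disjoint and cover the positive integers.
#'
#' @param threshold integer `T >= 2`.
#' @param body a [tp_params()] object on `[1, T - 1]`.
#' @param tail a [bg_params()] object; with a spike its shift is `T` (tail
#'   models values `> T`), without one its shift is `T - 1` (values `>= T`).
#' @param weights numeric `(w_body, w_spike, w_tail)`, non-negative, summing
#'   to 1.
#' @return an object of class `"los_mixture"`.
#' @export
los_mixture <- function(threshold, body, tail, weights) {
  stopifnot(inherits(body, "tp_params"), inherits(tail, "bg_params"))
  if (threshold < 2 || threshold != round(threshold))
    stop("'threshold' must be an integer >= 2", call. = FALSE)
  if (length(weights) != 3L || any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop("'weights' must be 3 non-negative numbers summing to 1", call. = FALSE)
  # the tail shift encodes the spike convention: shift = T models values > T
  # (spike component owns T), shift = T - 1 models values >= T (no spike)
  if (!tail$shift %in% c(threshold, threshold - 1L))
    stop("tail shift must be 'threshold' (spike on) or 'threshold - 1' (spike off)",
         call. = FALSE)
  if (tail$shift == threshold - 1L && weights[2] > 0)
    stop("spike weight must be 0 when the tail covers the threshold value",
         call. = FALSE)
  names(weights) <- c("body", "spike", "tail")
  structure(list(threshold = as.integer(threshold), body = body,
                 spike_weight = unname(weights[2]), tail = tail,
                 weights = weights),
            class = "los_mixture")
}

#' @export
print.los_mixture <- function(x, ...) {
  cat(sprintf("LOS mixture at threshold %d\n", x$threshold))
  cat(sprintf("  body : truncated Poisson(rate = %.4g) on [%d, %g], weight %.4f\n",
              x$body$rate, x$body$lower, x$body$upper, x$weights[1]))
  cat(sprintf("  spike: mass %.4f at %d\n", x$weights[2], x$threshold))
  cat(sprintf("  tail : Beta-Geometric(%.4g, %.4g) shifted by %d, weight %.4f\n",
              x$tail$alpha, x$tail$beta, x$tail$shift, x$weights[3]))
  invisible(x)
}

#' Mixture PMF over the positive integers
#'
#' @param x integer vector.
#' @param mixture an [los_mixture()] object.
#' @export
mixture_pmf <- function(x, mixture) {
  stopifnot(inherits(mixture, "los_mixture"))
  w <- mixture$weights
  p <- w[1] * tp_pmf(x, mixture$body)
  p <- p + w[2] * as.numeric(x == mixture$threshold)
  tl <- mixture$tail
  in_tail <- x > tl$shift
  if (any(in_tail)) p[in_tail] <- p[in_tail] + w[3] * bg_pmf(x[in_tail], tl)
  unname(p)
}

#' Sample from a threshold-split mixture
#'
#' @param n number of draws.
#' @param mixture an [los_mixture()] object.
#' @param seed optional integer seed (caller RNG state restored).
#' @export
mixture_sample <- function(n, mixture, seed = NULL) {
  stopifnot(inherits(mixture, "los_mixture"))
  with_seed(seed, {
    comp <- sample.int(3L, n, replace = TRUE, prob = mixture$weights)
    out <- numeric(n)
    nb <- sum(comp == 1L); ns <- sum(comp == 2L); nt <- sum(comp == 3L)
    if (nb) out[comp == 1L] <- tp_sample(nb, mixture$body)
    if (ns) out[comp == 2L] <- mixture$threshold
    if (nt) out[comp == 3L] <- bg_sample(nt, mixture$tail)
    out
  })
}

#' Fit a threshold-split mixture to length-of-stay data
#'
#' Strata are fit independently: truncated-Poisson MLE on the body
#' (`1 .. threshold - 1`), Beta-Geometric MLE on the shifted tail (subtract
#' the shift, fit, add it back), and empirical stratum proportions as the
#' mixing weights. With `spike = TRUE` the observations exactly at the
#' threshold form their own point-mass component and the tail stratum is the
#' values strictly above it; with `spike = FALSE` the threshold value joins
#' the tail stratum.
#'
#' @param sample integer durations.
#' @param threshold integer policy threshold `>= 2`.
#' @param spike model the mass at `threshold` as its own component?
#' @return an [los_mixture()] object with attribute `tail_fit` (the full
#'   [fit_betageometric()] result).
#' @export
fit_mixture <- function(sample, threshold, spike = TRUE) {
  x <- as_los_values(sample)
  if (threshold < 2 || threshold != round(threshold))
    stop("'threshold' must be an integer >= 2", call. = FALSE)
  body_x <- x[x < threshold]
  if (length(body_x) == 0) stop("empty body stratum (no values below threshold)", call. = FALSE)
  if (spike) {
    n_spike <- sum(x == threshold)
    tail_x <- x[x > threshold]
    tail_shift <- as.integer(threshold)
  } else {
    n_spike <- 0L
    tail_x <- x[x >= threshold]
    tail_shift <- as.integer(threshold - 1L)
  }
  if (length(tail_x) == 0) stop("empty tail stratum (no values in the tail)", call. = FALSE)
  body <- fit_trunc_poisson(body_x, 1L, threshold - 1L)
  tail_fit <- fit_betageometric(tail_x, shift = tail_shift)
  if (is.null(tail_fit$params)) stop("tail stratum fit failed: ", tail_fit$message, call. = FALSE)
  w <- c(length(body_x), n_spike, length(tail_x)) / length(x)
  out <- los_mixture(threshold, body, tail_fit$params, w)
  attr(out, "tail_fit") <- tail_fit
  out
}

# ---- discrete two-sample Kolmogorov-Smirnov ---------------------------------

#' Discrete two-sample Kolmogorov-Smirnov test
#'
#' The D-statistic is the maximum absolute difference between the two
#' empirical CDFs, evaluated over the union of observed values (the correct
#' evaluation grid for integer-valued data, where ties are the norm). The
#' critical value at level `level` uses the asymptotic two-sample formula
#' `c(level) * sqrt((n + m) / (n m))` with
#' `c(level) = sqrt(-log(level / 2) / 2)` (1.358 at the 5% level); for
#' discrete data this is conservative. An optional permutation p-value
#' (pooled-sample label shuffles) gives an exact-under-exchangeability
#' alternative.
#'
#' @param a,b numeric samples (non-empty).
#' @param level significance level.
#' @param p_value if `TRUE`, compute a permutation p-value.
#' @param n_perm number of permutation resamples.
#' @param seed optional integer seed for the permutations.
#' @return an object of class `"ks_discrete"`: `d_stat`, `n`, `m`, `level`,
#'   `critical_value`, `reject`, `p_value` (or `NA`).
#' @export
ks_two_sample_discrete <- function(a, b, level = 0.05, p_value = FALSE,
                                   n_perm = 2000L, seed = NULL) {
  a <- as_los_values(a, min_value = -Inf)
  b <- as_los_values(b, min_value = -Inf)
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  n <- length(a); m <- length(b)
  d <- ks_d_stat(a, b)
  cc <- sqrt(-log(level / 2) / 2)
  crit <- cc * sqrt((n + m) / (n * m))
  pv <- NA_real_
  if (p_value) {
    pool <- c(a, b)
    pv <- with_seed(seed, {
      ge <- 0L
      for (i in seq_len(n_perm)) {
        idx <- sample.int(n + m, n)
        if (ks_d_stat(pool[idx], pool[-idx]) >= d - 1e-12) ge <- ge + 1L
      }
      (1 + ge) / (n_perm + 1)
    })
  }
  structure(list(d_stat = d, n = n, m = m, level = level,
                 critical_value = crit, reject = d > crit, p_value = pv),
            class = "ks_discrete")
}

ks_d_stat <- function(a, b) {
  u <- sort(unique(c(a, b)))
  fa <- findInterval(u, sort(a)) / length(a)
  fb <- findInterval(u, sort(b)) / length(b)
  max(abs(fa - fb))
}

#' @export
print.ks_discrete <- function(x, ...) {
  cat(sprintf("Discrete two-sample KS: D = %.4f (n = %d, m = %d)\n",
              x$d_stat, x$n, x$m))
  cat(sprintf("  critical value at level %.2g: %.4f -> %s\n",
              x$level, x$critical_value,
              if (x$reject) "reject equality" else "no evidence against equality"))
  if (!is.na(x$p_value)) cat(sprintf("  permutation p-value: %.4g\n", x$p_value))
  if (!is.null(attr(x, "m_mc"))) cat(sprintf("  Monte-Carlo sample: m = %d, seed = %s\n",
                                             attr(x, "m_mc"), format(attr(x, "seed"))))
  invisible(x)
}

#' Monte-Carlo goodness of fit for a fitted LOS model
#'
#' Draws `m` values from the fitted model (a [bg_params()] law or an
#' [los_mixture()]) under `seed` and compares them with the observed sample
#' through [ks_two_sample_discrete()] at the given level. The seed and `m`
#' are recorded on the result so the test is reproducible.
#'
#' @param sample observed integer durations.
#' @param model a [bg_params()] or [los_mixture()] object.
#' @param m Monte-Carlo sample size (1e5 by default).
#' @param seed optional integer seed.
#' @param level significance level.
#' @return a `"ks_discrete"` result with attributes `m_mc` and `seed`.
#' @export
gof_monte_carlo <- function(sample, model, m = 1e5, seed = NULL, level = 0.05) {
  sim <- if (inherits(model, "bg_params")) bg_sample(m, model, seed = seed)
  else if (inherits(model, "los_mixture")) mixture_sample(m, model, seed = seed)
  else stop("'model' must be a 'bg_params' or 'los_mixture' object", call. = FALSE)
  out <- ks_two_sample_discrete(sample, sim, level = level)
  attr(out, "m_mc") <- as.integer(m)
  attr(out, "seed") <- seed
  out
}
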