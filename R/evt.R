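#' Empirical mean excess (mean residual life) curve
#'
#' For each threshold `a`, `ME(a)` is the mean of `x - a` over the
#' observations strictly above `a`: the expected remaining stay of a patient
#' already admitted for `a` days. Thresholds are the sorted distinct sample
#' values below the maximum (LOS is integer and sparse in the tail, so a
#' fixed grid would mostly hit empty cells). The shape of the curve separates
#' three regimes: decreasing (thin tails with memory), constant
#' (memorylessness, geometric/exponential), increasing (heavy "Lindy" tails,
#' where the longer the stay so far, the longer the expected remainder).
#'
#' @param sample integer durations (or an `los_sample`).
#' @param trim_top_fraction fraction of the highest thresholds to drop from
#'   the returned curve; near the sample maximum the empirical curve bends
#'   down for lack of higher observations (finite-sample bias), not because
#'   the tail thins.
#' @return a data frame of class `"mean_excess_curve"` with columns
#'   `threshold`, `me`, `tail_count`.
#' @export
mean_excess <- function(sample, trim_top_fraction = 0) {
  x <- as_los_values(sample)
  if (length(x) < 2) stop("need at least 2 observations", call. = FALSE)
  if (length(unique(x)) < 2) {
    warning("all observations equal: mean excess curve is empty")
    out <- data.frame(threshold = numeric(0), me = numeric(0), tail_count = integer(0))
    class(out) <- c("mean_excess_curve", "data.frame")
    return(out)
  }
  xs <- sort(x)
  n <- length(xs)
  u <- unique(xs)
  u <- u[-length(u)]                       # no tail beyond the maximum
  cs <- cumsum(xs)
  idx <- findInterval(u, xs)               # observations <= threshold
  tail_count <- n - idx
  tail_sum <- cs[n] - cs[idx]
  me <- tail_sum / tail_count - u
  if (trim_top_fraction > 0) {
    keep <- seq_len(max(1L, floor(length(u) * (1 - trim_top_fraction))))
    u <- u[keep]; me <- me[keep]; tail_count <- tail_count[keep]
  }
  out <- data.frame(threshold = u, me = me, tail_count = tail_count)
  class(out) <- c("mean_excess_curve", "data.frame")
  out
}

#' Maximum-to-sum ratio trajectory
#'
#' Running ratio `R_k = max(x_1^p, ..., x_k^p) / sum(x_1^p, ..., x_k^p)` in
#' sample order, for moment order `p` in 1..4. `R_n -> 0` as `n` grows iff
#' the p-th moment is finite; a trajectory that refuses to vanish is the
#' visual signature of a diverging (or very slowly converging) moment.
#'
#' @param sample positive durations, in observation order.
#' @param p moment order, one of 1, 2, 3, 4.
#' @return a data frame of class `"max_to_sum_curve"` with columns `k`,
#'   `ratio`, and attribute `p`.
#' @export
max_to_sum <- function(sample, p = 1L) {
  x <- as_los_values(sample, min_value = -Inf)
  if (!p %in% 1:4) stop("'p' must be one of 1, 2, 3, 4", call. = FALSE)
  if (any(x <= 0)) stop("all values must be positive", call. = FALSE)
  xp <- x^p
  out <- data.frame(k = seq_along(x), ratio = cummax(xp) / cumsum(xp))
  attr(out, "p") <- as.integer(p)
  class(out) <- c("max_to_sum_curve", "data.frame")
  out
}

#' Exponential QQ plot of log-transformed data
#'
#' A log-transformed Pareto variable is exponential, so plotting the order
#' statistics of `log(x)` against standard-exponential quantiles at plotting
#' positions `i / (n + 1)` is a visual heavy-tail test: an (eventually)
#' linear pattern is consistent with a generalized-Pareto right tail.
#'
#' @param sample durations, all `>= 1` (logs of sub-unit stays are not
#'   meaningful here).
#' @return a data frame of class `"qq_exp_plot"` with columns `theoretical`
#'   and `empirical` (both non-decreasing) and attribute `r`, the Pearson
#'   correlation of the two sequences.
#' @export
qq_exponential_log <- function(sample) {
  x <- as_los_values(sample, min_value = -Inf)
  if (any(x < 1)) stop("all values must be >= 1", call. = FALSE)
  if (length(unique(x)) < 2)
    stop("constant sample: QQ correlation is undefined", call. = FALSE)
  n <- length(x)
  emp <- sort(log(x))
  theo <- stats::qexp(seq_len(n) / (n + 1))
  out <- data.frame(theoretical = theo, empirical = emp)
  attr(out, "r") <- stats::cor(theo, emp)
  class(out) <- c("qq_exp_plot", "data.frame")
  out
}

#' Empirical subexponentiality ratio
#'
#' Estimates `(1 - F2(x)) / (1 - F(x))` where `F2` is the CDF of the sum of
#' two independent copies: for subexponential laws this ratio tends to 2 as
#' `x` grows (two patients jointly exceeding a high threshold is twice as
#' likely as one of them doing so — the single large observation dominates
#' the sum). Given a [bg_params()] law, two independent seeded samples of
#' size `n_sim` are drawn; given a data sample, it is split at random into
#' two halves to manufacture independence.
#'
#' @param source a [bg_params()] object or a sample of durations.
#' @param thresholds evaluation thresholds; defaults to the 99th to 99.9th
#'   percentiles of the single-copy sample.
#' @param n_sim simulation size per copy when `source` is a parameter set
#'   (at least 1e5; far-tail survival probabilities need it).
#' @param seed optional integer seed.
#' @return a data frame of class `"subexp_ratio_curve"` with columns
#'   `threshold`, `ratio`, `se` (binomial standard error of the ratio),
#'   `surv_one`, `surv_sum`. Thresholds where either survival estimate is
#'   zero are omitted.
#' @export
subexp_ratio <- function(source, thresholds = NULL, n_sim = 1e6, seed = NULL) {
  if (inherits(source, "bg_params")) {
    if (n_sim < 1e5) stop("'n_sim' must be at least 1e5 for tail estimation", call. = FALSE)
    xs <- with_seed(seed, list(bg_sample(n_sim, source), bg_sample(n_sim, source)))
    x1 <- xs[[1]]; x2 <- xs[[2]]
  } else {
    x <- as_los_values(source)
    if (length(x) < 4) stop("need at least 4 observations to split", call. = FALSE)
    half <- floor(length(x) / 2)
    idx <- with_seed(seed, sample.int(length(x), 2 * half))
    x1 <- x[idx[seq_len(half)]]
    x2 <- x[idx[half + seq_len(half)]]
  }
  if (is.null(thresholds)) {
    thresholds <- unique(round(stats::quantile(x1, seq(0.99, 0.999, by = 0.001),
                                               names = FALSE, type = 1)))
  }
  n1 <- length(x1)
  sm <- x1 + x2
  s1 <- vapply(thresholds, function(t) mean(x1 > t), numeric(1))
  s2 <- vapply(thresholds, function(t) mean(sm > t), numeric(1))
  keep <- s1 > 0 & s2 > 0
  thresholds <- thresholds[keep]; s1 <- s1[keep]; s2 <- s2[keep]
  ratio <- s2 / s1
  se <- ratio * sqrt((1 - s1) / (s1 * n1) + (1 - s2) / (s2 * n1))
  out <- data.frame(threshold = thresholds, ratio = ratio, se = se,
                    surv_one = s1, surv_sum = s2)
  class(out) <- c("subexp_ratio_curve", "data.frame")
  out
}
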