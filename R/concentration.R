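#' Sample Gini index
#'
#' `G = 2 * sum(i * x_(i)) / (n * sum(x)) - (n + 1) / n` over the ascending
#' order statistics: 0 for perfect equality, approaching 1 as the total
#' concentrates in a few observations (the "80-20" Pareto rule corresponds
#' to roughly 0.76). The plain sample formula is the default; the
#' `n / (n - 1)` small-sample correction is available but negligible at
#' registry sample sizes.
#'
#' @param sample non-negative values, at least one positive.
#' @param unbiased apply the `n / (n - 1)` correction?
#' @return the Gini index in `[0, 1]`.
#' @export
gini <- function(sample, unbiased = FALSE) {
  x <- as_los_values(sample, min_value = -Inf)
  if (any(x < 0)) stop("values must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero sample: Gini index undefined", call. = FALSE)
  n <- length(x)
  xs <- sort(x)
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  if (unbiased) g <- g * n / (n - 1)
  g
}

#' Bootstrap Gini estimate
#'
#' Nonparametric bootstrap (resampling observations with replacement) for
#' the standard error and a percentile confidence interval of the Gini
#' index.
#'
#' @param sample non-negative values.
#' @param n_boot number of bootstrap resamples.
#' @param conf confidence level for the percentile interval.
#' @param seed optional integer seed (caller RNG state restored).
#' @param unbiased passed to [gini()].
#' @return an object of class `"gini_estimate"`: `gini`, `se`,
#'   `ci` (length 2), `conf`, `n_boot`, `seed`, `n`.
#' @export
gini_bootstrap <- function(sample, n_boot = 1000L, conf = 0.95, seed = NULL,
                           unbiased = FALSE) {
  x <- as_los_values(sample, min_value = -Inf)
  point <- gini(x, unbiased = unbiased)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) gini(x[sample.int(length(x), replace = TRUE)],
                            unbiased = unbiased),
           numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha)))
  structure(list(gini = point, se = stats::sd(reps), ci = ci, conf = conf,
                 n_boot = as.integer(n_boot), seed = seed, n = length(x)),
            class = "gini_estimate")
}

#' @export
print.gini_estimate <- function(x, ...) {
  cat(sprintf("Gini index: %.4f (bootstrap SE %.5f, %g%% CI [%.4f, %.4f], B = %d, n = %d)\n",
              x$gini, x$se, 100 * x$conf, x$ci[1], x$ci[2], x$n_boot, x$n))
  invisible(x)
}

#' Lorenz curve of total LOS concentration
#'
#' Step curve from (0, 0) to (1, 1): with `reversed = FALSE` the horizontal
#' axis is the cumulative fraction of units ordered by increasing value (the
#' classical convex Lorenz curve); with `reversed = TRUE` units are ordered
#' by decreasing value, so the curve reads "the top x% of admissions
#' concentrate y% of total LOS".
#'
#' @param sample non-negative values.
#' @param reversed order units by decreasing value?
#' @return a data frame of class `"lorenz_curve"` with columns
#'   `population_fraction` and `value_fraction` (both from 0 to 1) and
#'   attribute `reversed`.
#' @export
lorenz <- function(sample, reversed = FALSE) {
  x <- as_los_values(sample, min_value = -Inf)
  if (any(x < 0)) stop("values must be non-negative", call. = FALSE)
  if (sum(x) == 0) stop("all-zero sample: Lorenz curve undefined", call. = FALSE)
  xs <- sort(x, decreasing = reversed)
  n <- length(xs)
  out <- data.frame(population_fraction = c(0, seq_len(n) / n),
                    value_fraction = c(0, cumsum(xs) / sum(xs)))
  attr(out, "reversed") <- reversed
  class(out) <- c("lorenz_curve", "data.frame")
  out
}

#' Smallest population share holding a given share of total value
#'
#' Ordering units by decreasing value, returns the smallest fraction of
#' units whose values sum to at least `value_share` of the total (e.g. "x%
#' of patients concentrate 50% of LOS").
#'
#' @param sample non-negative values.
#' @param value_share target share of the total, in (0, 1].
#' @return the population fraction in (0, 1].
#' @export
concentration_share <- function(sample, value_share) {
  x <- as_los_values(sample, min_value = -Inf)
  if (!is.numeric(value_share) || length(value_share) != 1L ||
      value_share <= 0 || value_share > 1)
    stop("'value_share' must be in (0, 1]", call. = FALSE)
  if (sum(x) == 0) stop("all-zero sample", call. = FALSE)
  xs <- sort(x, decreasing = TRUE)
  k <- which(cumsum(xs) >= value_share * sum(xs) - 1e-12)[1]
  k / length(xs)
}

#' Elbow (knee) point of a curve
#'
#' The point of maximum perpendicular distance to the chord joining the
#' curve's endpoints; ties are broken toward smaller `x`. When the largest
#' distance, relative to the chord length, is below `tol` the curve is
#' declared straight and no elbow is reported.
#'
#' @param x,y curve coordinates (at least 3 points), or `x` a two-column
#'   data frame / matrix.
#' @param tol relative chord-distance tolerance below which no elbow exists.
#' @return an object of class `"elbow_point"`: `found`, `index`, `x`, `y`,
#'   `distance` (perpendicular), `rel_distance`.
#' @export
find_elbow <- function(x, y = NULL, tol = 1e-3) {
  if (is.null(y)) {
    xy <- as.data.frame(x)
    if (ncol(xy) < 2) stop("curve must have two columns", call. = FALSE)
    y <- xy[[2]]; x <- xy[[1]]
  }
  if (length(x) < 3) stop("need at least 3 points", call. = FALSE)
  o <- order(x)
  x <- x[o]; y <- y[o]
  n <- length(x)
  dx <- x[n] - x[1]; dy <- y[n] - y[1]
  chord <- sqrt(dx^2 + dy^2)
  if (chord == 0) stop("degenerate curve: identical endpoints", call. = FALSE)
  # perpendicular distance from each interior point to the endpoint chord
  d <- abs(dy * (x - x[1]) - dx * (y - y[1])) / chord
  d[c(1, n)] <- -Inf
  i <- which.max(d)                       # which.max takes the first (smallest x) tie
  rel <- d[i] / chord
  structure(list(found = rel >= tol, index = i, x = x[i], y = y[i],
                 distance = d[i], rel_distance = rel),
            class = "elbow_point")
}

#' @export
print.elbow_point <- function(x, ...) {
  if (x$found)
    cat(sprintf("Elbow at point %d: (%g, %g), relative chord distance %.4g\n",
                x$index, x$x, x$y, x$rel_distance))
  else
    cat(sprintf("No elbow: curve is straight to relative tolerance (max %.3g)\n",
                x$rel_distance))
  invisible(x)
}

#' Average daily charge as a function of LOS
#'
#' Groups a department's admissions by their exact integer LOS and averages
#' the per-admission daily charge (total charge divided by LOS) within each
#' group. Optionally restricted to admissions with a positive or negative
#' discharge outcome (see [classify_status()]).
#'
#' @param records an admission cohort (see [read_records()] /
#'   [generate_cohort()]).
#' @param department department token to select.
#' @param status_filter `NULL`, `"positive"`, or `"negative"`.
#' @return a data frame of class `"charge_curve"` with columns `los`,
#'   `mean_daily_charge` (THB/day), `n`.
#' @export
charge_per_day_curve <- function(records, department, status_filter = NULL) {
  rec <- records[records$department == department, , drop = FALSE]
  if (nrow(rec) == 0)
    stop(sprintf("department '%s' absent from the cohort", department), call. = FALSE)
  if (!is.null(status_filter)) {
    status_filter <- match.arg(status_filter, c("positive", "negative"))
    rec <- rec[classify_status(rec$discharge_status) == status_filter, , drop = FALSE]
    if (nrow(rec) == 0)
      stop(sprintf("no admissions with %s discharge status", status_filter), call. = FALSE)
  }
  daily <- rec$total_charge / rec$los
  agg <- stats::aggregate(daily, by = list(los = rec$los), FUN = mean)
  cnt <- as.data.frame(table(rec$los), stringsAsFactors = FALSE)
  out <- data.frame(los = agg$los, mean_daily_charge = agg$x,
                    n = cnt$Freq[match(agg$los, as.numeric(cnt$Var1))])
  out <- out[order(out$los), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("charge_curve", "data.frame")
  out
}

# weighted Pearson correlation (weights = admission counts per LOS value)
weighted_pearson <- function(x, y, w) {
  w <- w / sum(w)
  mx <- sum(w * x); my <- sum(w * y)
  sxy <- sum(w * (x - mx) * (y - my))
  sx <- sqrt(sum(w * (x - mx)^2)); sy <- sqrt(sum(w * (y - my)^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sxy / (sx * sy)
}

#' Piecewise correlation of LOS with average daily charge
#'
#' Pearson correlation between the LOS value and the mean daily charge
#' within each of the supplied LOS ranges, computed over distinct LOS values
#' of the averaged curve (unweighted by default; set `weighted = TRUE` to
#' weight each LOS value by its admission count). When the underlying
#' admission records are supplied, the standard error and percentile
#' confidence interval per range are obtained by bootstrap-resampling
#' admissions and recomputing the whole curve.
#'
#' @param curve a [charge_per_day_curve()] result.
#' @param ranges list of inclusive integer ranges `c(lo, hi)`, disjoint and
#'   ordered.
#' @param records,department optional admission records for the bootstrap.
#' @param status_filter passed through to the bootstrap curve recomputation.
#' @param n_boot bootstrap resamples (0 disables the bootstrap).
#' @param conf confidence level.
#' @param seed optional integer seed.
#' @param weighted weight LOS values by admission counts?
#' @return a data frame of class `"piecewise_corr"` with columns `lo`, `hi`,
#'   `r`, `n_points`, `se`, `ci_low`, `ci_high`. Ranges with fewer than two
#'   distinct LOS values (or zero variance) report `r = NA`.
#' @export
piecewise_correlation <- function(curve, ranges, records = NULL, department = NULL,
                                  status_filter = NULL, n_boot = 0L, conf = 0.95,
                                  seed = NULL, weighted = FALSE) {
  stopifnot(inherits(curve, "charge_curve") || is.data.frame(curve))
  rng <- do.call(rbind, lapply(ranges, function(r) {
    if (length(r) != 2 || r[1] > r[2]) stop("each range must be c(lo, hi) with lo <= hi", call. = FALSE)
    data.frame(lo = r[1], hi = r[2])
  }))
  if (nrow(rng) > 1) {
    o <- order(rng$lo)
    rng <- rng[o, , drop = FALSE]
    if (any(rng$lo[-1] <= rng$hi[-nrow(rng)]))
      stop("ranges must be disjoint", call. = FALSE)
  }
  corr_on <- function(cv) {
    vapply(seq_len(nrow(rng)), function(i) {
      sub <- cv[cv$los >= rng$lo[i] & cv$los <= rng$hi[i], , drop = FALSE]
      if (nrow(sub) < 2 || stats::sd(sub$mean_daily_charge) == 0 || stats::sd(sub$los) == 0)
        return(NA_real_)
      if (weighted) weighted_pearson(sub$los, sub$mean_daily_charge, sub$n)
      else stats::cor(sub$los, sub$mean_daily_charge)
    }, numeric(1))
  }
  r <- corr_on(curve)
  npt <- vapply(seq_len(nrow(rng)), function(i)
    sum(curve$los >= rng$lo[i] & curve$los <= rng$hi[i]), numeric(1))
  se <- ci_lo <- ci_hi <- rep(NA_real_, nrow(rng))
  if (n_boot > 0) {
    if (is.null(records) || is.null(department))
      stop("bootstrap requires 'records' and 'department'", call. = FALSE)
    rec <- records[records$department == department, , drop = FALSE]
    reps <- with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        rb <- rec[sample.int(nrow(rec), replace = TRUE), , drop = FALSE]
        corr_on(charge_per_day_curve(rb, department, status_filter))
      }, numeric(nrow(rng)))
    })
    reps <- matrix(reps, nrow = nrow(rng))      # ranges x resamples
    alpha <- (1 - conf) / 2
    se <- apply(reps, 1, stats::sd, na.rm = TRUE)
    ci_lo <- apply(reps, 1, stats::quantile, probs = alpha, na.rm = TRUE, names = FALSE)
    ci_hi <- apply(reps, 1, stats::quantile, probs = 1 - alpha, na.rm = TRUE, names = FALSE)
  }
  out <- data.frame(lo = rng$lo, hi = rng$hi, r = r, n_points = npt,
                    se = se, ci_low = ci_lo, ci_high = ci_hi)
  class(out) <- c("piecewise_corr", "data.frame")
  out
}
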