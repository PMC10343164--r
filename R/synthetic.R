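#' Department configuration for the synthetic registry generator
#'
#' Describes one department of a synthetic admission registry: how many
#' patients it sees, how often they are readmitted, the law of their stay
#' durations, how the average daily charge depends on LOS, and the discharge
#' outcome mix. The generator emulates the structure of a real registry —
#' repeated admissions per patient, Beta-Geometric LOS tails, an optional
#' policy spike, piecewise-linear daily charges — not its census dynamics
#' (admission dates are placed uniformly in the window).
#'
#' @param name department token.
#' @param n_patients number of patients (`>= 1`).
#' @param admissions_per_patient one of `list(type = "degenerate")` (one
#'   admission each), `list(type = "geometric", mean = m)` (1 plus a
#'   geometric count, mean `m >= 1`), or
#'   `list(type = "histogram", counts = k, prob = p)`.
#' @param los_model a [bg_params()] law or an [los_mixture()] (the latter
#'   carries a policy spike explicitly).
#' @param charge_model `list(segments = data.frame(lo, hi, intercept, slope),
#'   noise_sd, min_daily)`: mean daily charge at LOS `x` inside a segment is
#'   `intercept + slope * x` THB/day, plus symmetric Gaussian noise, floored
#'   at `min_daily` (> 0). Segments must cover the LOS support without
#'   overlap; the last segment's `hi` may be `Inf`.
#' @param p_negative probability of a negative discharge outcome.
#' @param statuses list with character vectors `positive` and `negative` to
#'   draw labels from.
#' @param date_window two `Date`s (or ISO strings): earliest admission and
#'   latest discharge.
#' @return an object of class `"dept_config"`.
#' @export
dept_config <- function(name, n_patients,
                        admissions_per_patient = list(type = "degenerate"),
                        los_model,
                        charge_model = list(
                          segments = data.frame(lo = 1, hi = Inf,
                                                intercept = 5000, slope = 0),
                          noise_sd = 500, min_daily = 100),
                        p_negative = 0.02,
                        statuses = list(positive = c("Complete recovery", "Improved"),
                                        negative = c("Dead", "Not improved")),
                        date_window = as.Date(c("2017-02-15", "2018-09-30"))) {
  if (n_patients < 1 || n_patients != round(n_patients))
    stop("'n_patients' must be a positive integer", call. = FALSE)
  if (!inherits(los_model, "bg_params") && !inherits(los_model, "los_mixture"))
    stop("'los_model' must be a 'bg_params' or 'los_mixture' object", call. = FALSE)
  if (!admissions_per_patient$type %in% c("degenerate", "geometric", "histogram"))
    stop("unknown admissions_per_patient type", call. = FALSE)
  if (admissions_per_patient$type == "geometric" &&
      (is.null(admissions_per_patient$mean) || admissions_per_patient$mean < 1))
    stop("geometric admissions law needs mean >= 1", call. = FALSE)
  seg <- charge_model$segments
  if (!all(c("lo", "hi", "intercept", "slope") %in% names(seg)))
    stop("charge segments need columns lo, hi, intercept, slope", call. = FALSE)
  seg <- seg[order(seg$lo), , drop = FALSE]
  if (seg$lo[1] > 1 || any(seg$lo[-1] != seg$hi[-nrow(seg)] + 1))
    stop("charge segments must cover the LOS support contiguously from 1", call. = FALSE)
  if (p_negative < 0 || p_negative > 1) stop("'p_negative' must be in [0, 1]", call. = FALSE)
  date_window <- as.Date(date_window)
  if (length(date_window) != 2 || date_window[2] <= date_window[1])
    stop("'date_window' must be two increasing dates", call. = FALSE)
  structure(list(name = name, n_patients = as.integer(n_patients),
                 admissions_per_patient = admissions_per_patient,
                 los_model = los_model,
                 charge_model = list(segments = seg,
                                     noise_sd = charge_model$noise_sd %||% 500,
                                     min_daily = charge_model$min_daily %||% 100),
                 p_negative = p_negative, statuses = statuses,
                 date_window = date_window),
            class = "dept_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# noiseless mean daily charge at integer LOS values
charge_segment_value <- function(los, segments) {
  out <- numeric(length(los))
  for (i in seq_len(nrow(segments))) {
    in_seg <- los >= segments$lo[i] & los <= segments$hi[i]
    out[in_seg] <- segments$intercept[i] + segments$slope[i] * los[in_seg]
  }
  out
}

draw_admission_counts <- function(cfg) {
  app <- cfg$admissions_per_patient
  switch(app$type,
         degenerate = rep(1L, cfg$n_patients),
         geometric = 1L + stats::rgeom(cfg$n_patients, prob = 1 / app$mean),
         histogram = sample(app$counts, cfg$n_patients, replace = TRUE,
                            prob = app$prob))
}

#' Generate a synthetic admission cohort
#'
#' For each patient an admission count is drawn, each admission gets a LOS
#' from the department's model, an admission date uniform in the feasible
#' part of the window (discharge = admission + LOS), a daily charge equal to
#' the configured segment value at that LOS plus noise (floored at the
#' configured minimum), and a discharge status. Everything is reproducible
#' under the mandatory seed, and the realized ground truth is returned
#' alongside the cohort.
#'
#' @param configs a [dept_config()] or list of them.
#' @param seed integer seed (mandatory).
#' @return a list with `cohort` (an `"los_cohort"` data frame) and
#'   `ground_truth` (per department: the config, realized admission count,
#'   per-patient admission counts, and the noiseless charge curve).
#' @export
generate_cohort <- function(configs, seed) {
  if (missing(seed) || is.null(seed)) stop("'seed' is mandatory", call. = FALSE)
  if (inherits(configs, "dept_config")) configs <- list(configs)
  with_seed(seed, {
    parts <- list()
    truth <- list()
    for (cfg in configs) {
      counts <- draw_admission_counts(cfg)
      n_adm <- sum(counts)
      pid <- rep(sprintf("%s-P%06d", cfg$name, seq_along(counts)), counts)
      los <- if (inherits(cfg$los_model, "bg_params")) bg_sample(n_adm, cfg$los_model)
      else mixture_sample(n_adm, cfg$los_model)
      window_days <- as.numeric(cfg$date_window[2] - cfg$date_window[1])
      if (any(los > window_days))
        stop(sprintf("date window of %d days is shorter than a drawn LOS of %d days",
                     window_days, max(los)), call. = FALSE)
      offset <- floor(stats::runif(n_adm) * (window_days - los + 1))
      adm_date <- cfg$date_window[1] + offset
      daily <- charge_segment_value(los, cfg$charge_model$segments) +
        stats::rnorm(n_adm, 0, cfg$charge_model$noise_sd)
      daily <- pmax(daily, cfg$charge_model$min_daily)
      neg <- stats::runif(n_adm) < cfg$p_negative
      status <- character(n_adm)
      if (any(neg)) status[neg] <- sample(cfg$statuses$negative, sum(neg), replace = TRUE)
      if (any(!neg)) status[!neg] <- sample(cfg$statuses$positive, sum(!neg), replace = TRUE)
      parts[[cfg$name]] <- data.frame(
        admission_id = sprintf("%s-A%06d", cfg$name, seq_len(n_adm)),
        patient_id = pid,
        admission_date = adm_date,
        discharge_date = adm_date + los,
        los = los,
        total_charge = round(daily * los, 2),
        discharge_status = status,
        department = cfg$name,
        stringsAsFactors = FALSE)
      los_grid <- seq(1, min(max(cfg$charge_model$segments$hi), max(los)))
      truth[[cfg$name]] <- list(
        config = cfg,
        n_admissions = n_adm,
        admission_counts = counts,
        charge_curve = data.frame(
          los = los_grid,
          mean_daily_charge = charge_segment_value(los_grid,
                                                   cfg$charge_model$segments)))
    }
    cohort <- do.call(rbind, parts)
    rownames(cohort) <- NULL
    class(cohort) <- c("los_cohort", "data.frame")
    list(cohort = cohort, ground_truth = truth)
  })
}

# ---- presets ----------------------------------------------------------------

# Department presets: cohort sizes, readmission ratios, Beta-Geometric
# parameters (per-admission), policy spike, and charge-curve shapes follow
# the published registry the generator emulates; slopes/intercepts are
# chosen to give the reported piecewise-linear daily-charge behavior
# (decreasing then flat for the surgical wards, increasing for
# rehabilitation) at realistic THB magnitudes.
fixture_presets <- function() {
  list(
    surgery = list(
      n_patients = 14884, mean_adm = 1 / 0.8292,
      los_model = bg_params(7.027677, 38.58531),
      segments = data.frame(lo = c(1, 15, 31), hi = c(14, 30, Inf),
                            intercept = c(21000, 6000, 4400),
                            slope = c(-1150, -60, -2)),
      noise_sd = 600, p_negative = 0.03,
      positive = c("Complete recovery", "Improved")),
    obgyn = list(
      n_patients = 17483, mean_adm = 1 / 0.8775,
      los_model = bg_params(7.1307, 9.3826),
      segments = data.frame(lo = c(1, 12, 18), hi = c(11, 17, Inf),
                            intercept = c(16000, 5200, 4200),
                            slope = c(-1050, -70, -3)),
      noise_sd = 500, p_negative = 0.01,
      positive = c("Complete recovery", "Improved", "Delivered", "D/C with mother")),
    pediatrics = list(
      n_patients = 5086, mean_adm = 1 / 0.6782,
      los_model = bg_params(3.2695, 17.6431),
      segments = data.frame(lo = c(1, 14, 51), hi = c(13, 50, Inf),
                            intercept = c(18000, 5500, 3900),
                            slope = c(-1000, -35, -1)),
      noise_sd = 550, p_negative = 0.02,
      positive = c("Complete recovery", "Improved", "D/C with mother")),
    rehab = list(
      n_patients = 304, mean_adm = 1 / 0.3052,
      los_model = los_mixture(
        threshold = 20L,
        body = tp_params(14, 1L, 19L),
        tail = bg_params(37.3032, 387.4253, shift = 20L),
        weights = c(0.4000, 0.1146, 0.4854)),
      segments = data.frame(lo = c(1, 10, 40), hi = c(9, 39, Inf),
                            intercept = c(2000, 3900, 4700),
                            slope = c(250, 35, 12)),
      noise_sd = 300, p_negative = 1 / 994,
      positive = c("Complete recovery", "Improved")))
}

#' Preset synthetic department fixtures
#'
#' Ready-made [dept_config()]s for four archetypal specialty departments —
#' three with freely varying Beta-Geometric stays (surgery, obstetrics/
#' gynecology, pediatrics; heavy tails of decreasing severity) and one
#' rehabilitation ward whose stays are policy-censored at 20 days (truncated
#' Poisson body, 11.46% spike at 20, shifted Beta-Geometric tail, and a
#' patients-to-admissions ratio of 30.52%).
#'
#' @param name one of `"surgery"`, `"obgyn"`, `"pediatrics"`, `"rehab"`.
#' @param scale multiplies the patient count (e.g. `0.1` for a quick
#'   smoke-test cohort).
#' @param seed integer seed (mandatory).
#' @return as [generate_cohort()]: a list with `cohort` and `ground_truth`.
#' @export
make_fixture <- function(name = c("surgery", "obgyn", "pediatrics", "rehab"),
                         scale = 1, seed) {
  name <- match.arg(name)
  cfg <- fixture_config(name, scale)
  generate_cohort(list(cfg), seed = seed)
}

#' @rdname make_fixture
#' @export
fixture_config <- function(name = c("surgery", "obgyn", "pediatrics", "rehab"),
                           scale = 1) {
  name <- match.arg(name)
  p <- fixture_presets()[[name]]
  dept_config(
    name = name,
    n_patients = max(1L, round(p$n_patients * scale)),
    admissions_per_patient = if (p$mean_adm > 1)
      list(type = "geometric", mean = p$mean_adm) else list(type = "degenerate"),
    los_model = p$los_model,
    charge_model = list(segments = p$segments, noise_sd = p$noise_sd,
                        min_daily = 200),
    p_negative = p$p_negative,
    statuses = list(positive = p$positive,
                    negative = c("Dead", "Not improved", "D/C separately")))
}
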