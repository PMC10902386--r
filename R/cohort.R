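#' Synthetic smartphone-sensing cohort
#'
#' Tools to simulate a cohort of subjects carrying always-on smartphones:
#' a daily latent depression trait on the 0-100 CAT-DI scale, raw sensor
#' streams (GPS fixes, screen on/off events, call/SMS logs) whose daily
#' statistics are coupled to the latent trait through planted subject-specific
#' loadings, and a sparse (bi)weekly assessment series with dropout. Because
#' ground truth (latent trajectories, loadings) is returned alongside the raw
#' streams, every downstream stage of the pipeline can be verified against
#' known answers.
#'
#' @name cohort
NULL

# Features a loading may be planted on, and the daily driver each one acts on
# (logit of home dwell share, log venue rate, minutes of sleep, log call rate,
# log screen-session rate). Names match columns produced by the extraction
# modules.
LOADABLE_FEATURES <- c("time_at_home", "n_locations", "sleep_duration",
                       "calls_total", "screen_on_min")

# Reference magnitude of each loading on its driver's natural scale; the
# effect_heterogeneity knob multiplies these to spread per-subject loadings.
LOADING_SCALE <- c(time_at_home = 0.6, n_locations = 0.4,
                   sleep_duration = 35, calls_total = 0.35,
                   screen_on_min = 0.25)

#' Configuration of a synthetic cohort
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_days days of follow-up per subject (>= 30).
#' @param assessment_period_days days between scheduled assessments; 7
#'   emulates weekly assessment (in-person clinical care), 14 biweekly
#'   (online support).
#' @param dropout_hazard per-assessment probability of dropping out after the
#'   first assessment (geometric attrition).
#' @param sensor_missing_rate probability that a subject-day emits no sensor
#'   records at all (missing at random).
#' @param effect_heterogeneity spread of per-subject loadings around
#'   `loading_mu`, in units of each feature's reference magnitude; 0 gives
#'   every subject identical loadings.
#' @param noise_sd standard deviation of both the AR(1) component of the
#'   latent trait (stationary sd) and, unless `obs_noise_sd` is given, of the
#'   assessment observation noise, in CAT-DI points.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output.
#' @param trend_sd sd of the per-subject total linear drift over follow-up
#'   (CAT-DI points).
#' @param season_amp_sd sd of the half-normal seasonal sinusoid amplitude.
#' @param loading_mu named numeric vector of population-mean loadings, names
#'   from `time_at_home`, `n_locations`, `sleep_duration`, `calls_total`,
#'   `screen_on_min`. Units are per +1 SD of latent severity on each
#'   feature's driver scale. Zero everywhere gives a null cohort.
#' @param obs_noise_sd assessment observation noise sd; defaults to
#'   `noise_sd`.
#' @param android_prob probability a subject's device reports SMS (Android).
#' @param tz IANA timezone the cohort lives in.
#' @param origin_date local calendar date of study day 1.
#'
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects, n_days,
                          assessment_period_days = 14,
                          dropout_hazard = 0.02,
                          sensor_missing_rate = 0.1,
                          effect_heterogeneity = 1,
                          noise_sd = 5,
                          seed,
                          trend_sd = 10,
                          season_amp_sd = 8,
                          loading_mu = c(time_at_home = 0.6,
                                         n_locations = -0.4,
                                         sleep_duration = -35,
                                         calls_total = -0.35,
                                         screen_on_min = 0.25),
                          obs_noise_sd = NULL,
                          android_prob = 0.5,
                          tz = "America/Los_Angeles",
                          origin_date = "2021-01-04") {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("cohort_config: an integer 'seed' is mandatory")
  if (!is.numeric(n_subjects) || n_subjects < 1)
    stop("cohort_config: n_subjects must be >= 1")
  if (!is.numeric(n_days) || n_days < 30)
    stop("cohort_config: n_days must be >= 30")
  if (!assessment_period_days %in% c(7L, 14L))
    stop("cohort_config: assessment_period_days must be 7 or 14")
  for (p in c(dropout_hazard, sensor_missing_rate, android_prob))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("cohort_config: probabilities must lie in [0,1]")
  if (effect_heterogeneity < 0 || noise_sd < 0 || trend_sd < 0 ||
      season_amp_sd < 0)
    stop("cohort_config: spread parameters must be non-negative")
  if (length(loading_mu) == 0) loading_mu <- numeric(0)
  unknown <- setdiff(names(loading_mu), LOADABLE_FEATURES)
  if (length(unknown))
    stop("cohort_config: loading on unknown feature(s): ",
         paste(unknown, collapse = ", "))
  mu <- stats::setNames(numeric(length(LOADABLE_FEATURES)), LOADABLE_FEATURES)
  mu[names(loading_mu)] <- loading_mu
  structure(list(
    n_subjects = as.integer(n_subjects), n_days = as.integer(n_days),
    assessment_period_days = as.integer(assessment_period_days),
    dropout_hazard = dropout_hazard,
    sensor_missing_rate = sensor_missing_rate,
    effect_heterogeneity = effect_heterogeneity,
    noise_sd = noise_sd, seed = as.integer(seed),
    trend_sd = trend_sd, season_amp_sd = season_amp_sd,
    loading_mu = mu,
    obs_noise_sd = if (is.null(obs_noise_sd)) noise_sd else obs_noise_sd,
    android_prob = android_prob, tz = tz, origin_date = origin_date
  ), class = "cohort_config")
}

subject_ids <- function(config) sprintf("S%03d", seq_len(config$n_subjects))

# Deterministic per-subject, per-purpose stream seed below 2^31.
stream_seed <- function(config, subject_idx, salt) {
  (config$seed %% 100000L) * 20011L + subject_idx * 1009L + salt
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Simulate cohort-level ground truth
#'
#' Draws subject-level parameters (intercepts, trends, seasonal terms,
#' loadings, venue geometry, sleep schedules, platform flags, sensor-missing
#' day masks) and the full daily latent mood trajectories.
#'
#' @param config a [cohort_config()].
#' @return a list of class `cohort_truth` with elements `latent_mood`
#'   (n_days x n_subjects matrix, values in `[0,100]`), `loadings`
#'   (n_subjects x feature matrix), `venues`, `schedules`, `android`,
#'   `missing_days`, and the per-subject trajectory parameters.
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  ns <- config$n_subjects; nd <- config$n_days
  ids <- subject_ids(config)

  intercept <- rtruncnorm1(ns, 55, 15, 5, 95)
  drift <- stats::rnorm(ns, 0, config$trend_sd)
  amp <- abs(stats::rnorm(ns, 0, config$season_amp_sd))
  period <- stats::runif(ns, 60, 120)
  phase <- stats::runif(ns, 0, 2 * pi)

  phi <- 0.9
  innov_sd <- config$noise_sd * sqrt(1 - phi^2)
  latent <- matrix(NA_real_, nd, ns, dimnames = list(NULL, ids))
  t_ <- seq_len(nd)
  for (s in seq_len(ns)) {
    ar <- numeric(nd)
    ar[1] <- stats::rnorm(1, 0, config$noise_sd)
    if (nd > 1) {
      e <- stats::rnorm(nd - 1, 0, innov_sd)
      for (d in 2:nd) ar[d] <- phi * ar[d - 1] + e[d - 1]
    }
    traj <- intercept[s] + drift[s] * (t_ - 1) / max(nd - 1, 1) +
      amp[s] * sin(2 * pi * t_ / period[s] + phase[s]) + ar
    latent[, s] <- pmin(100, pmax(0, traj))
  }

  nf <- length(LOADABLE_FEATURES)
  z <- matrix(stats::rnorm(ns * nf), ns, nf)
  loadings <- matrix(rep(config$loading_mu, each = ns), ns, nf,
                     dimnames = list(ids, LOADABLE_FEATURES)) +
    config$effect_heterogeneity *
    matrix(rep(LOADING_SCALE, each = ns), ns, nf) * z

  # Venue geometry: per-subject home plus 4 satellite venues spaced >= 2 km
  # so the 400 m clustering radius separates them unambiguously.
  venues <- lapply(seq_len(ns), function(s) {
    base_lat <- 33.5 + 0.02 * s
    base_lon <- -118.5 + 0.005 * s
    k <- 1:4
    data.frame(
      venue = c("home", paste0("v", k)),
      lat = c(base_lat, base_lat + 0.022 * k),
      lon = c(base_lon, base_lon + 0.010 * ((-1)^k))
    )
  })
  names(venues) <- ids

  schedules <- data.frame(
    subject = ids,
    bed_min = stats::rnorm(ns, 1410, 25),        # ~23:30, minutes from midnight
    sleep_base_min = stats::rnorm(ns, 480, 20)   # baseline sleep duration
  )
  android <- stats::runif(ns) < config$android_prob
  missing_days <- matrix(stats::runif(nd * ns) < config$sensor_missing_rate,
                         nd, ns, dimnames = list(NULL, ids))

  structure(list(
    latent_mood = latent, loadings = loadings, venues = venues,
    schedules = schedules, android = stats::setNames(android, ids),
    missing_days = missing_days,
    params = data.frame(subject = ids, intercept = intercept, drift = drift,
                        amp = amp, period = period, phase = phase)
  ), class = "cohort_truth")
}

#' Daily latent mood for one subject
#'
#' Subject-specific intercept (the dominant variance component) plus a slow
#' linear trend, a seasonal sinusoid, and AR(1) noise, clipped to `[0,100]`.
#'
#' @param config a [cohort_config()].
#' @param subject subject id (e.g. `"S001"`) or index.
#' @param truth optional precomputed [simulate_truth()]; regenerated when
#'   absent.
#' @return numeric vector of length `n_days` in `[0,100]`.
#' @export
simulate_latent_mood <- function(config, subject, truth = NULL) {
  if (is.null(truth)) truth <- simulate_truth(config)
  idx <- subject_index(config, subject)
  truth$latent_mood[, idx]
}

subject_index <- function(config, subject) {
  if (is.numeric(subject)) return(as.integer(subject))
  idx <- match(subject, subject_ids(config))
  if (is.na(idx)) stop("unknown subject: ", subject)
  idx
}

# Standardized severity used by all mood->behavior couplings.
mood_z <- function(latent) (latent - 55) / 15

# Epoch seconds of local midnight for study days 1..n_days (+1 for spillover).
day_starts <- function(config) {
  dates <- as.Date(config$origin_date) + seq_len(config$n_days + 1L) - 1L
  as.numeric(as.POSIXct(paste(dates, "00:00:00"), tz = config$tz))
}

#' Simulate raw sensor streams for one subject
#'
#' GPS fixes are emitted as noisy dwells at the subject's venues, with the
#' daily home-dwell share and the number of venues visited modulated by latent
#' mood through the planted loadings. Screen events carry a nightly off-period
#' whose duration tracks mood; daytime screen sessions and call/SMS counts are
#' Poisson with log-rates linear in mood. Days flagged sensor-missing emit no
#' records. Timestamps are Unix milliseconds (UTC).
#'
#' @inheritParams simulate_latent_mood
#' @param streams which streams to generate (see [simulate_cohort()]).
#' @return list with raw `gps`, `screen`, `comm` data frames (AWARE-style
#'   columns) for that subject; streams not requested come back empty.
#' @export
simulate_sensors <- function(config, truth, subject,
                             streams = c("gps", "screen", "comm")) {
  stopifnot(inherits(truth, "cohort_truth"))
  idx <- subject_index(config, subject)
  id <- subject_ids(config)[idx]
  latent <- truth$latent_mood[, idx]
  mz <- mood_z(latent)
  load <- truth$loadings[idx, ]
  ven <- truth$venues[[id]]
  sched <- truth$schedules[idx, ]
  miss <- truth$missing_days[, idx]
  nd <- config$n_days
  starts <- day_starts(config)

  # --- nightly sleep schedule (night d = sleep ending morning of day d) ---
  set.seed(stream_seed(config, idx, 1L))
  bed_min <- stats::rnorm(nd, sched$bed_min, 15)            # on evening d-1
  dur_min <- pmax(120, pmin(840, sched$sleep_base_min +
    load["sleep_duration"] * mz + stats::rnorm(nd, 0, 15)))
  wake_min <- pmax(60, pmin(719, bed_min - 1440 + dur_min)) # morning of day d

  # --- GPS ---
  set.seed(stream_seed(config, idx, 4L))
  home_share <- stats::plogis(stats::qlogis(0.45) +
    load["time_at_home"] * mz + stats::rnorm(nd, 0, 0.15))
  n_away <- pmin(4L, stats::rpois(nd, exp(log(2) + load["n_locations"] * mz)))

  gps_t <- vector("list", nd); gps_v <- vector("list", nd)
  for (d in seq_len(nd)) {
    if (miss[d] || !"gps" %in% streams) next
    wk <- wake_min[d]
    ft <- cumsum(stats::runif(ceiling(1440 / 3.5), 2.5, 6))
    ft <- ft[ft < 1439]
    # itinerary: home until wake; waking time alternates home / away venues
    k <- n_away[d]
    venue_of <- rep(1L, length(ft))
    if (k > 0) {
      waking <- 1439 - wk
      away_tot <- waking * (1 - home_share[d])
      seg <- away_tot / k
      gap <- (waking - away_tot) / (k + 1)
      which_v <- 1L + sample.int(4L, k)
      for (j in seq_len(k)) {
        a0 <- wk + gap * j + seg * (j - 1)
        venue_of[ft >= a0 & ft < a0 + seg] <- which_v[j]
      }
    }
    m <- length(ft)
    lat <- ven$lat[venue_of] + stats::rnorm(m, 0, 15 / 111320)
    lon <- ven$lon[venue_of] +
      stats::rnorm(m, 0, 15 / (111320 * cos(ven$lat[1] * pi / 180)))
    gps_t[[d]] <- starts[d] + ft * 60
    gps_v[[d]] <- cbind(lat, lon)
  }
  gps <- if (length(unlist(gps_t))) {
    xy <- do.call(rbind, gps_v)
    data.frame(subject = id,
               timestamp = round(unlist(gps_t) * 1000),
               double_latitude = xy[, 1], double_longitude = xy[, 2])
  } else empty_raw("gps", id)

  # --- screen ---
  set.seed(stream_seed(config, idx, 5L))
  n_sess <- stats::rpois(nd, exp(log(18) + load["screen_on_min"] * mz))
  scr_t <- vector("list", nd); scr_s <- vector("list", nd)
  for (d in seq_len(nd)) {
    if (miss[d] || !"screen" %in% streams) next
    tt <- numeric(0); ss <- integer(0)
    # wake: phone comes on (also ends the previous night's off period)
    tt <- c(tt, wake_min[d] * 60, wake_min[d] * 60 + 1)
    ss <- c(ss, 1L, 3L)                        # on, unlocked
    if (n_sess[d] > 0) {
      s0 <- sort(stats::runif(n_sess[d], wake_min[d] + 10,
                              min(bed_min[d + 1], 1439, na.rm = TRUE) - 10))
      len <- pmax(0.5, stats::rexp(n_sess[d], 1 / 7))
      s1 <- pmin(s0 + len, 1439.5)
      keep <- which(c(TRUE, s0[-1] > cummax(s1[-length(s1)])[seq_len(
        max(n_sess[d] - 1, 0))]))
      for (j in keep) {
        tt <- c(tt, s0[j] * 60, s0[j] * 60 + 1, s1[j] * 60)
        ss <- c(ss, 1L, 3L, 0L)
      }
    }
    # bed: a short phone check ending at the final off event (night d+1)
    if (d < nd) {
      bm <- bed_min[d + 1]
      bt <- if (bm <= 1439) starts[d] + bm * 60 else starts[d + 1] +
        (bm - 1440) * 60
      if (bt < starts[nd + 1]) {
        tt <- c(tt, bt - starts[d] - 480, bt - starts[d] - 479,
                bt - starts[d])
        ss <- c(ss, 1L, 3L, 0L)
      }
    }
    # occasional night interruption during sleep of night d
    if (stats::runif(1) < 0.05 && wake_min[d] > 90) {
      it <- stats::runif(1, 30, wake_min[d] - 30)
      tt <- c(tt, it * 60, it * 60 + 120)
      ss <- c(ss, 1L, 0L)
    }
    o <- order(tt)
    scr_t[[d]] <- starts[d] + tt[o]
    scr_s[[d]] <- ss[o]
  }
  # bed_min is indexed by night; pad lookup used above
  screen <- if (length(unlist(scr_t))) {
    data.frame(subject = id,
               timestamp = round(unlist(scr_t) * 1000),
               screen_status = unlist(scr_s))
  } else empty_raw("screen", id)

  # --- communication ---
  set.seed(stream_seed(config, idx, 2L))
  contacts <- sprintf("c%02d", 1:8)
  n_call <- stats::rpois(nd, exp(log(3) + load["calls_total"] * mz))
  n_sms <- if (truth$android[idx]) stats::rpois(nd, 5) else rep(0L, nd)
  comm_rows <- vector("list", nd)
  for (d in seq_len(nd)) {
    if (miss[d] || !"comm" %in% streams || (n_call[d] + n_sms[d]) == 0) next
    nc <- n_call[d]; nsm <- n_sms[d]
    tt <- stats::runif(nc + nsm, wake_min[d] + 5, 1435)
    comm_rows[[d]] <- data.frame(
      subject = id,
      timestamp = round((starts[d] + tt * 60) * 1000),
      comm_type = c(rep("call", nc), rep("sms", nsm)),
      comm_direction = ifelse(stats::runif(nc + nsm) < 0.55,
                              "outgoing", "incoming"),
      duration_s = c(round(stats::rexp(nc, 1 / 180)), rep(NA_real_, nsm)),
      contact = sample(contacts, nc + nsm, replace = TRUE))
  }
  comm <- if (any(!vapply(comm_rows, is.null, TRUE)))
    do.call(rbind, comm_rows) else empty_raw("comm", id)

  list(gps = gps, screen = screen, comm = comm)
}

empty_raw <- function(kind, id = character(0)) {
  switch(kind,
    gps = data.frame(subject = character(0), timestamp = numeric(0),
                     double_latitude = numeric(0),
                     double_longitude = numeric(0)),
    screen = data.frame(subject = character(0), timestamp = numeric(0),
                        screen_status = integer(0)),
    comm = data.frame(subject = character(0), timestamp = numeric(0),
                      comm_type = character(0),
                      comm_direction = character(0),
                      duration_s = numeric(0), contact = character(0)))
}

#' Extracted features mechanically driven by a planted loading
#'
#' Each loadable driver moves a whole family of extracted features, not just
#' its namesake: a higher home-dwell share shortens away-venue dwells (so
#' the dwell filter retains fewer venues, lowering entropy and span), longer
#' sleep delays the first morning interaction and inflates time at home, and
#' so on. This ground-truth map — feature name to the sign of its response
#' per unit positive loading — is what recovery analyses should check
#' against, since an elastic net may surface any member of a mechanically
#' coupled family.
#'
#' @param feature one of the loadable feature names (see
#'   [cohort_config()]'s `loading_mu`).
#' @return named numeric vector: responding extracted features, each +1 or
#'   -1.
#' @export
driven_features <- function(feature) {
  switch(feature,
    time_at_home = c(time_at_home = 1, time_at_home_day = 1,
                     time_at_home_evening = 1, transit_share = -1,
                     n_locations = -1, n_locations_day = -1,
                     n_locations_evening = -1, entropy = -1,
                     entropy_day = -1, entropy_evening = -1,
                     norm_entropy = -1, venue_span_m = -1, distance_m = -1,
                     n_transitions = -1),
    n_locations = c(n_locations = 1, n_locations_day = 1,
                    n_locations_evening = 1, entropy = 1, entropy_day = 1,
                    entropy_evening = 1, venue_span_m = 1, distance_m = 1,
                    n_transitions = 1, transit_share = 1),
    sleep_duration = c(sleep_duration = 1, waketime_min = 1,
                       longest_off_end_min = 1,
                       first_morning_interaction_min = 1, time_at_home = 1,
                       time_at_home_night = 1, first_move_min = 1),
    calls_total = c(calls_total = 1, calls_in = 1, calls_out = 1,
                    call_minutes = 1, call_minutes_in = 1,
                    call_minutes_out = 1, comm_total = 1,
                    unique_contacts_calls = 1, unique_contacts_total = 1),
    screen_on_min = c(screen_on_min = 1, unlock_count = 1,
                      n_off_periods = 1),
    stop("unknown loadable feature: ", feature))
}

#' Simulate sparse assessments for one subject
#'
#' Assessments follow the configured cadence starting at day 1; each observed
#' score is the latent mood plus observation noise, clipped to `[0,100]`.
#' After the first assessment the subject drops out with probability
#' `dropout_hazard` before each subsequent one (geometric attrition).
#'
#' @inheritParams simulate_latent_mood
#' @param truth a [simulate_truth()] result.
#' @return data frame with columns subject, day, score.
#' @export
simulate_assessments <- function(config, truth, subject) {
  idx <- subject_index(config, subject)
  id <- subject_ids(config)[idx]
  latent <- truth$latent_mood[, idx]
  set.seed(stream_seed(config, idx, 3L))
  days <- seq(1L, config$n_days, by = config$assessment_period_days)
  if (length(days) > 1) {
    surv <- stats::runif(length(days) - 1) >= config$dropout_hazard
    keep <- c(TRUE, cumprod(surv) == 1)
    days <- days[keep]
  }
  score <- pmin(100, pmax(0, latent[days] +
    stats::rnorm(length(days), 0, config$obs_noise_sd)))
  data.frame(subject = id, day = days, score = score)
}

#' Simulate a full cohort
#'
#' Runs [simulate_truth()], [simulate_sensors()] and [simulate_assessments()]
#' for every subject and row-binds the streams.
#'
#' @param config a [cohort_config()].
#' @param streams which raw streams to generate; dropping `"gps"` gives a
#'   reduced cohort (screen/communication features only) that is much
#'   cheaper for large null-calibration runs. Per-stream random draws are
#'   independent, so the streams generated are identical whether or not the
#'   others are requested.
#' @return list of class `cohort` with raw `gps`, `screen`, `comm` streams
#'   (empty tables for streams not generated), `assessments`, the `truth`,
#'   and the `config`.
#' @export
simulate_cohort <- function(config, streams = c("gps", "screen", "comm")) {
  truth <- simulate_truth(config)
  ids <- subject_ids(config)
  sens <- lapply(seq_along(ids),
                 function(s) simulate_sensors(config, truth, s, streams))
  ass <- lapply(seq_along(ids),
                function(s) simulate_assessments(config, truth, s))
  structure(list(
    gps = do.call(rbind, lapply(sens, `[[`, "gps")),
    screen = do.call(rbind, lapply(sens, `[[`, "screen")),
    comm = do.call(rbind, lapply(sens, `[[`, "comm")),
    assessments = do.call(rbind, ass),
    truth = truth, config = config
  ), class = "cohort")
}

#' Simulate a single-dominant-loading recovery cohort
#'
#' A cohort built for planted-effect recovery analyses: every subject has
#' exactly one nonzero loading (cycled over the loadable features, random
#' sign, `magnitude` reference units), and latent mood is rebuilt with a
#' fixed-amplitude sinusoid plus mild AR(1) noise so each subject's
#' severity genuinely varies — a coupling whose driver never moves is
#' unrecoverable by any method, so flat trajectories would test nothing.
#'
#' @param n_subjects,n_days cohort dimensions.
#' @param seed integer seed.
#' @param magnitude loading strength in units of each feature's reference
#'   magnitude.
#' @param amplitude sinusoid amplitude of the latent trait, severity
#'   points.
#' @param ... further arguments to [cohort_config()].
#' @return list: `cohort` (as [simulate_cohort()]) and `planted`
#'   (data frame subject / feature / sign).
#' @export
simulate_recovery_cohort <- function(n_subjects, n_days, seed,
                                     magnitude = 3, amplitude = 15, ...) {
  cfg <- cohort_config(n_subjects = n_subjects, n_days = n_days,
                       seed = seed, dropout_hazard = 0,
                       effect_heterogeneity = 0,
                       loading_mu = numeric(0), ...)
  truth <- simulate_truth(cfg)
  feats <- colnames(truth$loadings)
  truth$loadings[, ] <- 0
  set.seed(cfg$seed + 1L)
  ids <- subject_ids(cfg)
  planted <- data.frame(subject = ids,
                        feature = feats[((seq_len(n_subjects) - 1) %%
                                           length(feats)) + 1],
                        sign = sample(c(-1, 1), n_subjects, replace = TRUE))
  phi <- 0.9
  for (s in seq_len(n_subjects)) {
    f <- planted$feature[s]
    truth$loadings[s, f] <- planted$sign[s] * magnitude * LOADING_SCALE[f]
    per <- stats::runif(1, 60, 120)
    ph <- stats::runif(1, 0, 2 * pi)
    ar <- as.numeric(stats::arima.sim(list(ar = phi), n_days,
                                      sd = cfg$noise_sd * sqrt(1 - phi^2)))
    truth$latent_mood[, s] <- pmin(100, pmax(0,
      truth$params$intercept[s] +
        amplitude * sin(2 * pi * seq_len(n_days) / per + ph) + ar))
  }
  sens <- lapply(seq_len(n_subjects),
                 function(s) simulate_sensors(cfg, truth, s))
  ass <- do.call(rbind, lapply(seq_len(n_subjects),
                               function(s) simulate_assessments(cfg, truth, s)))
  cohort <- structure(list(
    gps = do.call(rbind, lapply(sens, `[[`, "gps")),
    screen = do.call(rbind, lapply(sens, `[[`, "screen")),
    comm = do.call(rbind, lapply(sens, `[[`, "comm")),
    assessments = ass, truth = truth, config = cfg), class = "cohort")
  list(cohort = cohort, planted = planted)
}

#' Write cohort streams and ground truth to CSV
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("gps.csv", "screen.csv", "comm.csv",
                            "assessments.csv", "truth_latent.csv",
                            "truth_loadings.csv"))
  utils::write.csv(cohort$gps, paths[1], row.names = FALSE)
  utils::write.csv(cohort$screen, paths[2], row.names = FALSE)
  utils::write.csv(cohort$comm, paths[3], row.names = FALSE)
  utils::write.csv(cohort$assessments, paths[4], row.names = FALSE)
  lat <- cohort$truth$latent_mood
  utils::write.csv(data.frame(day = seq_len(nrow(lat)), lat, check.names = FALSE),
                   paths[5], row.names = FALSE)
  utils::write.csv(data.frame(subject = rownames(cohort$truth$loadings),
                              cohort$truth$loadings, check.names = FALSE),
                   paths[6], row.names = FALSE)
  invisible(paths)
}

#' Read a cohort configuration from a YAML file
#'
#' @param path YAML file whose keys are [cohort_config()] arguments; `seed`
#'   is mandatory.
#' @return a `cohort_config`.
#' @export
cohort_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("cohort_config_from_yaml requires the 'yaml' package")
  args <- yaml::read_yaml(path)
  if (!is.null(args$loading_mu)) args$loading_mu <- unlist(args$loading_mu)
  do.call(cohort_config, args)
}
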