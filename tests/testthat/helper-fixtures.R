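# Shared fixtures and independent brute-force oracles.
# Heavy cohort runs are cached per session so several tests can share them.

.moodcast_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .moodcast_cache))
    assign(key, force(expr), envir = .moodcast_cache)
  get(key, envir = .moodcast_cache)
}

# small cohort with strong heterogeneous couplings, shared by pipeline tests
small_cohort <- function() cached("small_cohort", {
  cfg <- cohort_config(n_subjects = 5, n_days = 100,
                       assessment_period_days = 7, dropout_hazard = 0,
                       sensor_missing_rate = 0.1, effect_heterogeneity = 2,
                       noise_sd = 3, seed = 2024)
  simulate_cohort(cfg)
})

# end-to-end cohort with strong heterogeneous couplings (40 x 200)
endtoend_run <- function() cached("endtoend_run", {
  cfg <- cohort_config(n_subjects = 40, n_days = 200,
                       assessment_period_days = 7, dropout_hazard = 0.02,
                       sensor_missing_rate = 0.1, effect_heterogeneity = 2,
                       noise_sd = 3, seed = 101)
  ch <- simulate_cohort(cfg)
  pl <- run_pipeline(ch, latent_method = "cs24", family = "logistic",
                     seed = 101)
  list(cohort = ch, pipeline = pl)
})

# 200-subject cohort with zero couplings and flat latent structure
null_run <- function() cached("null_run", {
  cfg <- cohort_config(n_subjects = 200, n_days = 120,
                       assessment_period_days = 7, dropout_hazard = 0,
                       sensor_missing_rate = 0.1, effect_heterogeneity = 0,
                       noise_sd = 5, trend_sd = 0, season_amp_sd = 0,
                       loading_mu = numeric(0), seed = 202)
  ch <- simulate_cohort(cfg, streams = c("screen", "comm"))
  run_pipeline(ch, latent_method = "locf", family = "logistic",
               modes = "idiographic", groups = "rhythm_social",
               expand = FALSE, seed = 202)
})

# matched clean/corrupted pipeline pair for leakage checks
leakage_pair <- function() cached("leakage_pair", {
  ch <- small_cohort()
  feats <- cached("small_features_all", extract_cohort_features(ch))
  pl1 <- cached("small_pipeline", run_pipeline(
    ch, latent_method = "locf", family = "logistic",
    modes = c("baseline", "idiographic"), features = feats,
    min_sensor_days = 30))
  feats2 <- feats
  for (id in names(pl1$splits)) {
    sp <- pl1$splits[[id]]
    feats2[[id]][(sp$split_day + 1):nrow(feats2[[id]]), ] <- 1e6
  }
  ch2 <- ch
  for (id in names(pl1$splits)) {
    sp <- pl1$splits[[id]]
    sel <- ch2$assessments$subject == id & ch2$assessments$day > sp$split_day
    ch2$assessments$score[sel] <- pmin(100, ch2$assessments$score[sel] + 33)
  }
  pl2 <- run_pipeline(ch2, latent_method = "locf", family = "logistic",
                      modes = c("baseline", "idiographic"),
                      features = feats2, min_sensor_days = 30)
  list(clean = pl1, corrupted = pl2)
})

# raw GPS table for one synthetic day: dwells at given venues
# venues: data.frame(lat, lon, start_min, end_min); gap_min between fixes
make_gps_day <- function(venues, gap_min = 4, noise_m = 10, seed = 1,
                         day = 1, tz = "America/Los_Angeles",
                         origin_date = "2021-01-04") {
  set.seed(seed)
  day_start <- as.numeric(as.POSIXct(paste(
    as.Date(origin_date) + day - 1, "00:00:00"), tz = tz))
  rows <- lapply(seq_len(nrow(venues)), function(i) {
    tt <- seq(venues$start_min[i], venues$end_min[i], by = gap_min)
    data.frame(
      subject = "S001",
      timestamp = round((day_start + tt * 60) * 1000),
      double_latitude = venues$lat[i] + rnorm(length(tt), 0, noise_m / 111320),
      double_longitude = venues$lon[i] +
        rnorm(length(tt), 0, noise_m / (111320 * cos(venues$lat[i] * pi / 180))))
  })
  do.call(rbind, rows)
}

# raw screen table from (min_of_day, state) pairs on one day
make_screen_events <- function(mins, states, day = 1,
                               tz = "America/Los_Angeles",
                               origin_date = "2021-01-04") {
  code <- c(off = 0L, on = 1L, lock = 2L, unlock = 3L)
  day_start <- as.numeric(as.POSIXct(paste(
    as.Date(origin_date) + day - 1, "00:00:00"), tz = tz))
  data.frame(subject = "S001",
             timestamp = round((day_start + mins * 60) * 1000),
             screen_status = unname(code[states]))
}

norm_screen <- function(mins, states, ...) {
  s <- normalize_stream(make_screen_events(mins, states, ...), "screen")
  annotate_days(s, "2021-01-04")
}

# ---- independent oracles ----

bf_entropy <- function(p) {
  tot <- 0
  for (pi in p) if (pi > 0) tot <- tot - pi * log(pi)
  tot
}

bf_mape <- function(o, p, eps = 1) {
  keep <- !is.na(o) & !is.na(p)
  o <- o[keep]; p <- p[keep]
  vals <- numeric(length(o))
  for (i in seq_along(o)) vals[i] <- abs(o[i] - p[i]) / max(o[i], eps)
  100 * sum(vals) / length(vals)
}

bf_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x^2) - sx^2) * (n * sum(y^2) - sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_one_sided = stats::pt(t, n - 2, lower.tail = FALSE))
}

bf_bh_reject <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= q * i / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

bf_locf <- function(days, scores, grid) {
  sapply(grid, function(d) {
    i <- which(days <= d)
    scores[max(i)]
  })
}

bf_roll_mean <- function(x, w, t, min_obs) {
  idx <- (t - w):(t - 1)
  idx <- idx[idx >= 1]
  v <- x[idx]
  if (sum(!is.na(v)) < min_obs) return(NA_real_)
  mean(v, na.rm = TRUE)
}
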