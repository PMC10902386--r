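#' Sleep, circadian, social, and device-usage features
#'
#' Sleep is proxied by the longest phone-off period in a 20:00-12:00 search
#' window around each night: its start and end estimate bedtime and waketime.
#' Night-time phone use, interruption counts, the circadian nadir of
#' interactions (circular kernel density), and first/last interaction times
#' complete 13 sleep features. Communication logs give 18 social features
#' (SMS ones only on Android devices), and screen logs give 2 device-usage
#' features (unlock count, screen-on minutes).
#'
#' @name rhythm_social_features
NULL

SLEEP_SEARCH_START <- -240   # 20:00 previous day, minutes relative to midnight
SLEEP_SEARCH_END <- 720      # 12:00

# off/lock -> next on/unlock intervals within [lo, hi) minutes relative to
# the night's midnight; intervals crossing the window edges are truncated.
off_periods <- function(ev_min, ev_state, lo = SLEEP_SEARCH_START,
                        hi = SLEEP_SEARCH_END) {
  ord <- order(ev_min)
  m <- ev_min[ord]; st <- ev_state[ord]
  is_off <- st %in% c("off", "lock")
  is_on <- st %in% c("on", "unlock")
  out <- NULL
  i <- 1
  while (i <= length(m)) {
    if (is_off[i]) {
      j <- i + 1
      while (j <= length(m) && !is_on[j]) j <- j + 1
      if (j <= length(m)) {
        a <- max(m[i], lo); b <- min(m[j], hi)
        if (b > a) out <- rbind(out, c(a, b, 1))
        i <- j
      } else {
        # trailing off period never closed by an on event: truncated at the
        # window edge and flagged, since its true end is unobserved
        a <- max(m[i], lo)
        if (hi > a) out <- rbind(out, c(a, hi, 0))
        break
      }
    } else i <- i + 1
  }
  if (is.null(out))
    data.frame(start = numeric(0), end = numeric(0), closed = logical(0))
  else data.frame(start = out[, 1], end = out[, 2], closed = out[, 3] == 1)
}

# screen-on minutes within [lo, hi): on/unlock -> next off/lock intervals;
# count_open = FALSE ignores a trailing on interval never closed by an off
# (used for night usage, where the post-wake stretch is not phone *use*)
screen_on_minutes <- function(ev_min, ev_state, lo, hi, count_open = TRUE) {
  ord <- order(ev_min)
  m <- ev_min[ord]; st <- ev_state[ord]
  total <- 0; cur_on <- NA_real_
  for (i in seq_along(m)) {
    if (st[i] %in% c("on", "unlock")) {
      if (is.na(cur_on)) cur_on <- m[i]
    } else if (st[i] %in% c("off", "lock")) {
      if (!is.na(cur_on)) {
        a <- max(cur_on, lo); b <- min(m[i], hi)
        if (b > a) total <- total + (b - a)
        cur_on <- NA_real_
      }
    }
  }
  if (!is.na(cur_on) && count_open) {
    a <- max(cur_on, lo)
    if (hi > a) total <- total + (hi - a)
  }
  total
}

#' Circadian nadir of phone interactions
#'
#' Circular Gaussian kernel density (period 24 h, bandwidth 1 h) over the
#' day's interaction clock-times, minimized on a 1-minute grid; ties return
#' the earliest minute.
#'
#' @param min_of_day numeric vector of event clock-times in minutes.
#' @return nadir clock time in minutes after midnight, or `NA` with fewer
#'   than 3 interactions.
#' @export
interaction_nadir <- function(min_of_day) {
  x <- min_of_day[!is.na(min_of_day)] %% 1440
  if (length(x) < 3) return(NA_real_)
  grid <- 0:1439
  bw <- 60
  d <- abs(outer(x, grid, "-"))
  d <- pmin(d, 1440 - d)              # circular distance, period 24 h
  dens <- colSums(stats::dnorm(d, sd = bw))
  grid[which.min(dens)]
}

#' Sleep features for one night
#'
#' The night labeled `day` spans 20:00 of day `day - 1` to 12:00 of `day`.
#'
#' @param screen normalized, day-annotated screen stream for one subject
#'   (from [annotate_days()]).
#' @param day integer study day whose morning ends the night.
#' @return named numeric vector of 13 sleep features (NA when no screen
#'   events fall in the search window).
#' @export
sleep_daily_features <- function(screen, day) {
  feat <- c(sleep_duration = NA_real_, bedtime_min = NA_real_,
            waketime_min = NA_real_, night_usage_min = NA_real_,
            nadir_min = NA_real_, last_night_interaction_min = NA_real_,
            first_morning_interaction_min = NA_real_,
            n_night_interruptions = NA_real_, n_off_periods = NA_real_,
            mean_off_period_min = NA_real_, longest_off_start_min = NA_real_,
            longest_off_end_min = NA_real_, screen_on_window_min = NA_real_)
  sel <- (screen$day == day - 1L & screen$min_of_day >= 1200) |
         (screen$day == day & screen$min_of_day < 720)
  ev <- screen[sel, , drop = FALSE]
  if (nrow(ev) == 0) return(feat)
  # minutes relative to the night's midnight (start of `day`)
  rel <- ifelse(ev$day == day, ev$min_of_day, ev$min_of_day - 1440)
  op <- off_periods(rel, ev$state)
  # plausible sleep candidates: closed off periods that start before 04:00
  # and reach past midnight (guards against days whose bed or wake events
  # fell on a sensor-missing neighbor day)
  cand <- op[op$closed & op$start < 240 & op$end > 0, , drop = FALSE]
  if (nrow(op) == 0) {
    feat["sleep_duration"] <- 0        # phone never off in the window
    feat["n_off_periods"] <- 0
  } else {
    feat["n_off_periods"] <- sum(op$closed)
    feat["mean_off_period_min"] <-
      if (any(op$closed)) mean((op$end - op$start)[op$closed]) else NA_real_
    if (nrow(cand) > 0) {
      len <- cand$end - cand$start
      k <- which.max(len)
      feat["sleep_duration"] <- len[k]
      feat["longest_off_start_min"] <- cand$start[k]
      feat["longest_off_end_min"] <- cand$end[k]
      # bed/wake as signed minutes from midnight (23:30 -> -30)
      feat["bedtime_min"] <- cand$start[k]
      feat["waketime_min"] <- cand$end[k]
    }
  }
  feat["night_usage_min"] <- screen_on_minutes(rel, ev$state, 0, 480,
                                               count_open = FALSE)
  feat["screen_on_window_min"] <-
    screen_on_minutes(rel, ev$state, SLEEP_SEARCH_START, SLEEP_SEARCH_END)
  inter <- rel[ev$state %in% c("on", "unlock")]
  night_int <- inter[inter >= 0 & inter < 360]
  feat["last_night_interaction_min"] <-
    if (length(night_int)) max(night_int) else NA_real_
  morn <- inter[inter >= 360 & inter < 720]
  feat["first_morning_interaction_min"] <-
    if (length(morn)) min(morn) else NA_real_
  feat["n_night_interruptions"] <- sum(inter >= 0 & inter < 480)
  feat
}

#' Social features for one day
#'
#' @param comm normalized, day-annotated communication stream for one
#'   subject.
#' @param day integer study day.
#' @param android whether SMS sensors are available (non-Android devices
#'   report NA for SMS features).
#' @return named numeric vector of 18 features.
#' @export
social_daily_features <- function(comm, day, android = TRUE) {
  ev <- comm[comm$day == day, , drop = FALSE]
  calls <- ev[ev$comm_type == "call", , drop = FALSE]
  sms <- ev[ev$comm_type == "sms", , drop = FALSE]
  out_c <- calls[calls$comm_direction == "outgoing", , drop = FALSE]
  in_c <- calls[calls$comm_direction == "incoming", , drop = FALSE]
  f <- c(
    calls_total = nrow(calls),
    calls_in = nrow(in_c),
    calls_out = nrow(out_c),
    call_minutes = sum(calls$duration_s, na.rm = TRUE) / 60,
    call_minutes_in = sum(in_c$duration_s, na.rm = TRUE) / 60,
    call_minutes_out = sum(out_c$duration_s, na.rm = TRUE) / 60,
    mean_call_min = if (nrow(calls)) mean(calls$duration_s) / 60 else NA_real_,
    pct_outgoing_calls = if (nrow(calls))
      100 * nrow(out_c) / nrow(calls) else NA_real_,
    unique_contacts_calls = length(unique(calls$contact)),
    prop_unique_out_calls = if (nrow(out_c))
      length(unique(out_c$contact)) / nrow(out_c) else NA_real_,
    comm_total = nrow(ev))
  if (android) {
    out_s <- sms[sms$comm_direction == "outgoing", , drop = FALSE]
    s <- c(
      sms_total = nrow(sms),
      sms_in = nrow(sms) - nrow(out_s),
      sms_out = nrow(out_s),
      unique_contacts_sms = length(unique(sms$contact)),
      prop_unique_out_sms = if (nrow(out_s))
        length(unique(out_s$contact)) / nrow(out_s) else NA_real_,
      unique_contacts_total = length(unique(ev$contact)),
      pct_outgoing_comm = if (nrow(ev)) 100 *
        mean(ev$comm_direction == "outgoing") else NA_real_)
  } else {
    s <- c(sms_total = NA_real_, sms_in = NA_real_, sms_out = NA_real_,
           unique_contacts_sms = NA_real_, prop_unique_out_sms = NA_real_,
           unique_contacts_total = length(unique(calls$contact)),
           pct_outgoing_comm = if (nrow(calls)) 100 *
             mean(calls$comm_direction == "outgoing") else NA_real_)
  }
  c(f, s)
}

#' Device-usage features for one day
#'
#' @param screen normalized, day-annotated screen stream for one subject.
#' @param day integer study day.
#' @return named vector: `unlock_count`, `screen_on_min`.
#' @export
device_usage_features <- function(screen, day) {
  ev <- screen[screen$day == day, , drop = FALSE]
  c(unlock_count = sum(ev$state == "unlock"),
    screen_on_min = screen_on_minutes(ev$min_of_day, ev$state, 0, 1440))
}

#' All daily screen and communication features for one subject
#'
#' @param screen normalized screen stream for one subject (may be empty).
#' @param comm normalized communication stream for one subject.
#' @param origin_date local date of study day 1.
#' @param n_days number of study days.
#' @param android whether SMS features are available.
#' @return data frame, one row per day: 13 sleep + 18 social + 2 device
#'   features. Days with no screen events get NA sleep/device features; days
#'   with no comm events get zero counts (a silent phone is an observation,
#'   not missingness) unless the whole day is sensor-missing, detected as no
#'   screen events either, in which case social features are NA too.
#' @export
rhythm_social_features <- function(screen, comm, origin_date, n_days,
                                   android = TRUE) {
  if (nrow(screen) > 0) screen <- annotate_days(screen, origin_date)
  if (nrow(comm) > 0) comm <- annotate_days(comm, origin_date)
  rows <- vector("list", n_days)
  screen_days <- if (nrow(screen)) unique(screen$day) else integer(0)
  for (d in seq_len(n_days)) {
    sl <- sleep_daily_features(screen, d)
    dev <- device_usage_features(screen, d)
    day_ev <- nrow(screen) > 0 && d %in% screen_days
    if (!day_ev) dev[] <- NA_real_
    soc <- social_daily_features(comm, d, android)
    if (!day_ev && all(is.na(sl))) soc[] <- NA_real_
    nad <- if (day_ev)
      interaction_nadir(screen$min_of_day[screen$day == d &
                          screen$state %in% c("on", "unlock")]) else NA_real_
    sl["nadir_min"] <- nad
    rows[[d]] <- c(sl, soc, dev)
  }
  out <- do.call(rbind, rows)
  data.frame(day = seq_len(n_days), out, check.names = FALSE)
}
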