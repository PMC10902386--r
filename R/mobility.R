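#' Daily mobility features from GPS
#'
#' Stationary fixes (average speed since the previous fix < 0.7 m/s) are
#' clustered per day by complete-linkage hierarchical clustering on
#' great-circle distance with an 800 m diameter cut, giving venues with a
#' consistent radius (<= 400 m from the centroid). Venues visited for less
#' than 15 minutes over the day are discarded as artifacts. Positions are
#' linearly interpolated on a 3-minute grid, a home venue is the cluster with
#' the most overnight (00:00-08:00) dwell, and time-at-home, location counts,
#' and location entropy are computed over the full day and the three 8-hour
#' windows.
#'
#' @name mobility_features
NULL

EARTH_RADIUS_M <- 6371000

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees (vectorized).
#' @return distance in meters on a 6,371,000 m sphere.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

#' Annotate GPS fixes with speed since the previous fix
#'
#' The first fix of each subject gets speed 0. Fixes with zero time gap but
#' nonzero displacement are dropped (logged in attribute `n_dropped`).
#'
#' @param fixes normalized GPS stream (columns subject, t, double_latitude,
#'   double_longitude), time-ordered within subject.
#' @return fixes with a `speed` column in m/s.
#' @export
annotate_speed <- function(fixes) {
  if (nrow(fixes) == 0) { fixes$speed <- numeric(0); return(fixes) }
  lat <- fixes$double_latitude; lon <- fixes$double_longitude
  n <- nrow(fixes)
  same <- c(FALSE, fixes$subject[-1] == fixes$subject[-n])
  dt <- c(NA_real_, as.numeric(fixes$t[-1]) - as.numeric(fixes$t[-n]))
  dist <- c(NA_real_, haversine_m(lat[-n], lon[-n], lat[-1], lon[-1]))
  speed <- ifelse(same, dist / dt, 0)
  bad <- same & dt == 0 & dist > 0
  speed[same & dt == 0 & dist == 0] <- 0
  speed[!same] <- 0
  fixes$speed <- speed
  out <- fixes[!bad, , drop = FALSE]
  attr(out, "n_dropped") <- sum(bad)
  out
}

STATIONARY_SPEED <- 0.7   # m/s, ~half average adult walking speed
CLUSTER_DIAMETER_M <- 800 # complete-linkage cut; venue radius <= 400 m
MIN_DWELL_MIN <- 15       # venues visited less than this per day are dropped
GRID_STEP_MIN <- 3        # interpolated position cadence

# spherical mean of coordinates in degrees
spherical_mean <- function(lat, lon) {
  r <- pi / 180
  x <- mean(cos(lat * r) * cos(lon * r))
  y <- mean(cos(lat * r) * sin(lon * r))
  z <- mean(sin(lat * r))
  c(lat = atan2(z, sqrt(x^2 + y^2)) / r, lon = atan2(y, x) / r)
}

#' Cluster one day's stationary fixes into venues
#'
#' @param stat data frame of one subject-day's stationary fixes with columns
#'   `min_of_day`, `double_latitude`, `double_longitude`, ordered in time.
#' @return list of class `venue_clustering`: `labels` (integer per fix, NA
#'   for fixes in discarded clusters), `centroids` (data frame cluster/lat/
#'   lon/first_visit), `dwell_min` per retained cluster. Empty clustering if
#'   no fixes.
#' @export
cluster_venues <- function(stat) {
  if (is.null(stat) || nrow(stat) == 0)
    return(structure(list(labels = integer(0),
                          centroids = data.frame(cluster = integer(0),
                                                 lat = numeric(0),
                                                 lon = numeric(0),
                                                 first_visit = numeric(0)),
                          dwell_min = numeric(0)),
                     class = "venue_clustering"))
  n <- nrow(stat)
  lat <- stat$double_latitude; lon <- stat$double_longitude
  if (n == 1) {
    raw_lab <- 1L
  } else {
    ii <- rep(seq_len(n - 1), times = (n - 1):1)
    jj <- sequence((n - 1):1) + ii
    dvec <- haversine_m(lat[ii], lon[ii], lat[jj], lon[jj])
    dd <- structure(dvec, Size = n, class = "dist", Diag = FALSE,
                    Upper = FALSE, method = "haversine")
    raw_lab <- stats::cutree(stats::hclust(dd, method = "complete"),
                             h = CLUSTER_DIAMETER_M)
  }
  # dwell: gap since previous stationary fix (capped) credited to the
  # current fix's cluster; first fix of the day credits nothing
  gap <- c(0, diff(stat$min_of_day))
  gap <- pmin(gap, 10)
  dwell <- tapply(gap, raw_lab, sum)
  keep <- as.integer(names(dwell)[dwell >= MIN_DWELL_MIN])
  # deterministic labels ordered by first visit time
  first_visit <- tapply(stat$min_of_day, raw_lab, min)
  keep <- keep[order(first_visit[as.character(keep)])]
  labels <- match(raw_lab, keep)              # NA for discarded clusters
  cm <- vapply(keep, function(kk)
    spherical_mean(lat[raw_lab == kk], lon[raw_lab == kk]), numeric(2))
  cent <- data.frame(cluster = seq_along(keep),
                     lat = if (length(keep)) cm[1, ] else numeric(0),
                     lon = if (length(keep)) cm[2, ] else numeric(0),
                     first_visit = as.numeric(first_visit[as.character(keep)]))
  structure(list(labels = labels, centroids = cent,
                 dwell_min = as.numeric(dwell[as.character(keep)])),
            class = "venue_clustering")
}

#' Interpolate positions on a 3-minute grid and label venue-or-transit states
#'
#' Positions are linearly interpolated between observed fixes on a 3-minute
#' grid spanning the day's first to last fix (no extrapolation). Each grid
#' point is assigned to the nearest retained venue if within 400 m of its
#' centroid, else labeled transit (state 0).
#'
#' @param day_fixes all of one subject-day's fixes (not just stationary),
#'   with `min_of_day`, `double_latitude`, `double_longitude`.
#' @param clustering a [cluster_venues()] result for the day.
#' @return data frame with `min_of_day`, `lat`, `lon`, `state` (venue label
#'   or 0 for transit). Length <= 1 rows when fewer than 2 fixes.
#' @export
interpolate_positions <- function(day_fixes, clustering) {
  if (nrow(day_fixes) < 2)
    return(data.frame(min_of_day = numeric(0), lat = numeric(0),
                      lon = numeric(0), state = integer(0)))
  m <- day_fixes$min_of_day
  grid <- seq(GRID_STEP_MIN * ceiling(m[1] / GRID_STEP_MIN),
              max(m), by = GRID_STEP_MIN)
  if (length(grid) == 0)
    return(data.frame(min_of_day = numeric(0), lat = numeric(0),
                      lon = numeric(0), state = integer(0)))
  lat <- stats::approx(m, day_fixes$double_latitude, grid, ties = "ordered")$y
  lon <- stats::approx(m, day_fixes$double_longitude, grid, ties = "ordered")$y
  cent <- clustering$centroids
  state <- rep(0L, length(grid))
  if (nrow(cent) > 0) {
    dmat <- sapply(seq_len(nrow(cent)), function(k)
      haversine_m(lat, lon, cent$lat[k], cent$lon[k]))
    dmat <- matrix(dmat, nrow = length(grid))
    nearest <- max.col(-dmat, ties.method = "first")
    near_d <- dmat[cbind(seq_along(grid), nearest)]
    state <- ifelse(near_d <= CLUSTER_DIAMETER_M / 2, cent$cluster[nearest], 0L)
  }
  data.frame(min_of_day = grid, lat = lat, lon = lon, state = state)
}

#' Assign the day's home venue
#'
#' Home is the venue with maximal dwell between local midnight and 08:00;
#' ties break toward the venue first visited earlier; `NA` if no overnight
#' venue dwell.
#'
#' @param trace an [interpolate_positions()] trace.
#' @param clustering the day's [cluster_venues()] result.
#' @return integer venue label or `NA`.
#' @export
assign_home <- function(trace, clustering) {
  night <- trace[trace$min_of_day < 480 & trace$state > 0, , drop = FALSE]
  if (nrow(night) == 0) return(NA_integer_)
  dwell <- table(night$state)
  best <- as.integer(names(dwell)[dwell == max(dwell)])
  if (length(best) > 1) {
    fv <- clustering$centroids$first_visit[match(best,
                                                 clustering$centroids$cluster)]
    best <- best[which.min(fv)]
  }
  best[1]
}

window_mask <- function(m, window) {
  switch(window,
    all = rep(TRUE, length(m)),
    night = m >= 0 & m < 480,
    day = m >= 480 & m < 960,
    evening = m >= 960)
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0) return(NA_real_)
  -sum(p * log(p))
}

#' Daily mobility features for one subject-day
#'
#' Time at home, number of venues visited, location entropy, and normalized
#' location entropy over the full day and the night/day/evening windows, plus
#' whole-day aggregates (transit share, distance traveled, venue span,
#' first/last movement time, venue transitions, max distance from home) for
#' a total of 23 activity features.
#'
#' @param trace an [interpolate_positions()] trace.
#' @param clustering the day's [cluster_venues()] result.
#' @param home home venue label (or `NA`).
#' @return named numeric vector of 23 features (NA where undefined).
#' @export
mobility_daily_features <- function(trace, clustering, home) {
  out <- c()
  for (w in c("all", "night", "day", "evening")) {
    suff <- if (w == "all") "" else paste0("_", w)
    sub <- trace[window_mask(trace$min_of_day, w), , drop = FALSE]
    if (nrow(sub) == 0) {
      v <- c(NA_real_, NA_real_, NA_real_, NA_real_)
    } else {
      at_venue <- sub$state[sub$state > 0]
      tah <- if (is.na(home)) NA_real_ else
        GRID_STEP_MIN * sum(sub$state == home)
      nloc <- length(unique(at_venue))
      if (nloc == 0) {
        ent <- NA_real_; nent <- NA_real_
      } else {
        p <- as.numeric(table(at_venue)) / length(at_venue)
        ent <- shannon_entropy(p)
        nent <- if (nloc <= 1) 0 else ent / log(nloc)
      }
      v <- c(tah, nloc, ent, nent)
    }
    names(v) <- paste0(c("time_at_home", "n_locations", "entropy",
                         "norm_entropy"), suff)
    out <- c(out, v)
  }
  n <- nrow(trace)
  if (n == 0) {
    extra <- rep(NA_real_, 7)
  } else {
    transit_share <- mean(trace$state == 0)
    dist_m <- if (n > 1) sum(haversine_m(trace$lat[-n], trace$lon[-n],
                                         trace$lat[-1], trace$lon[-1])) else 0
    cent <- clustering$centroids
    visited <- cent[cent$cluster %in% unique(trace$state[trace$state > 0]), ]
    span <- if (nrow(visited) > 1) {
      max(haversine_m(rep(visited$lat, each = nrow(visited)),
                      rep(visited$lon, each = nrow(visited)),
                      rep(visited$lat, times = nrow(visited)),
                      rep(visited$lon, times = nrow(visited))))
    } else 0
    moves <- which(c(FALSE, diff(trace$state) != 0))
    first_move <- if (length(moves)) trace$min_of_day[moves[1]] else NA_real_
    last_move <- if (length(moves))
      trace$min_of_day[moves[length(moves)]] else NA_real_
    n_trans <- sum(diff(trace$state[trace$state > 0]) != 0)
    max_home_d <- if (!is.na(home)) {
      hc <- cent[cent$cluster == home, ]
      max(haversine_m(trace$lat, trace$lon, hc$lat, hc$lon))
    } else NA_real_
    extra <- c(transit_share, dist_m, span, first_move, last_move,
               n_trans, max_home_d)
  }
  names(extra) <- c("transit_share", "distance_m", "venue_span_m",
                    "first_move_min", "last_move_min", "n_transitions",
                    "max_dist_home_m")
  c(out, extra)
}

#' All daily mobility features for one subject's GPS stream
#'
#' Runs speed annotation, per-day stationary filtering, venue clustering,
#' position interpolation, home assignment and feature extraction.
#'
#' @param gps normalized GPS stream for one subject.
#' @param origin_date local date of study day 1.
#' @param n_days number of study days.
#' @return data frame: one row per day with 23 feature columns (all NA on
#'   days without usable GPS).
#' @export
mobility_features <- function(gps, origin_date, n_days) {
  feat_names <- names(mobility_daily_features(
    data.frame(min_of_day = numeric(0), lat = numeric(0), lon = numeric(0),
               state = integer(0)),
    cluster_venues(NULL), NA_integer_))
  out <- matrix(NA_real_, n_days, length(feat_names),
                dimnames = list(NULL, feat_names))
  if (nrow(gps) > 0) {
    gps <- annotate_days(gps, origin_date)
    gps <- annotate_speed(gps)
    by_day <- split(seq_len(nrow(gps)), gps$day)
    for (dch in names(by_day)) {
      d <- as.integer(dch)
      if (d < 1 || d > n_days) next
      df <- gps[by_day[[dch]], , drop = FALSE]
      stat <- df[df$speed < STATIONARY_SPEED, , drop = FALSE]
      cl <- cluster_venues(stat)
      if (nrow(cl$centroids) == 0) next
      tr <- interpolate_positions(df, cl)
      home <- assign_home(tr, cl)
      out[d, ] <- mobility_daily_features(tr, cl, home)
    }
  }
  data.frame(day = seq_len(n_days), out, check.names = FALSE)
}
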