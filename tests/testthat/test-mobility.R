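# three venue centers >= 2 km apart, used throughout
VEN3 <- data.frame(lat = c(34.00, 34.03, 34.00),
                   lon = c(-118.00, -118.00, -117.965))

test_that("haversine agrees with geosphere on random coordinate pairs", {
  set.seed(10)
  for (i in 1:100) {
    p1 <- c(runif(1, -180, 180), runif(1, -80, 80))
    p2 <- p1 + runif(2, -0.5, 0.5)
    ours <- haversine_m(p1[2], p1[1], p2[2], p2[1])
    ref <- geosphere::distHaversine(p1, p2, r = 6371000)
    expect_equal(ours, ref, tolerance = 1e-9)
  }
})

test_that("speed annotation: stationary, moving, and single-fix cases", {
  t0 <- as.POSIXct("2021-01-04 10:00:00", tz = "UTC")
  f <- data.frame(subject = "S001", t = t0 + c(0, 60),
                  double_latitude = c(34, 34), double_longitude = c(-118, -118))
  expect_equal(annotate_speed(f)$speed, c(0, 0))

  # ~100 m north in 60 s -> ~1.667 m/s, not stationary
  f2 <- data.frame(subject = "S001", t = t0 + c(0, 60),
                   double_latitude = c(34, 34 + 100 / 111194.9),
                   double_longitude = c(-118, -118))
  sp <- annotate_speed(f2)$speed[2]
  expect_equal(sp, 100 / 60, tolerance = 0.01)
  expect_gt(sp, 0.7)

  f3 <- f[1, ]
  expect_equal(annotate_speed(f3)$speed, 0)
})

test_that("zero time gap with displacement drops the fix and logs it", {
  t0 <- as.POSIXct("2021-01-04 10:00:00", tz = "UTC")
  f <- data.frame(subject = "S001", t = t0 + c(0, 0, 60),
                  double_latitude = c(34, 34.01, 34.01),
                  double_longitude = -118)
  out <- annotate_speed(f)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_dropped"), 1)
})

test_that("fixes within 50 m form exactly one venue", {
  ven <- data.frame(lat = 34, lon = -118, start_min = 600, end_min = 660)
  raw <- make_gps_day(ven, noise_m = 15, seed = 2)
  g <- annotate_days(normalize_stream(raw, "gps"), "2021-01-04")
  cl <- cluster_venues(annotate_speed(g))
  expect_equal(nrow(cl$centroids), 1)
  expect_true(all(!is.na(cl$labels)))
})

test_that("three venues >= 2 km apart give three clusters with verified geometry", {
  ven <- cbind(VEN3, start_min = c(0, 600, 900), end_min = c(400, 700, 1000))
  raw <- make_gps_day(ven, seed = 3)
  g <- annotate_days(normalize_stream(raw, "gps"), "2021-01-04")
  g <- annotate_speed(g)
  stat <- g[g$speed < 0.7, ]
  cl <- cluster_venues(stat)
  expect_equal(nrow(cl$centroids), 3)
  # brute-force pairwise check: within-cluster diameters < 800 m,
  # between-cluster centroid distances > 2 km
  for (k in 1:3) {
    mem <- which(cl$labels == k)
    dmax <- max(outer(mem, mem, function(i, j)
      haversine_m(stat$double_latitude[i], stat$double_longitude[i],
                  stat$double_latitude[j], stat$double_longitude[j])))
    expect_lt(dmax, 800)
    cent <- cl$centroids[k, ]
    expect_lt(max(haversine_m(stat$double_latitude[mem],
                              stat$double_longitude[mem],
                              cent$lat, cent$lon)), 400)
  }
  cc <- cl$centroids
  expect_gt(min(haversine_m(cc$lat[c(1, 1, 2)], cc$lon[c(1, 1, 2)],
                            cc$lat[c(2, 3, 3)], cc$lon[c(2, 3, 3)])), 2000)
})

test_that("a five-minute stop is removed by the dwell filter", {
  ven <- cbind(rbind(VEN3, data.frame(lat = 34.06, lon = -118)),
               start_min = c(0, 600, 900, 800),
               end_min = c(400, 700, 1000, 805))
  raw <- make_gps_day(ven, seed = 4)
  g <- annotate_speed(annotate_days(normalize_stream(raw, "gps"),
                                    "2021-01-04"))
  cl <- cluster_venues(g[g$speed < 0.7, ])
  expect_equal(nrow(cl$centroids), 3)
  expect_true(all(cl$dwell_min >= 15))
})

test_that("clustering is invariant to input row order", {
  ven <- cbind(VEN3, start_min = c(0, 600, 900), end_min = c(400, 700, 1000))
  raw <- make_gps_day(ven, seed = 5)
  g <- annotate_speed(annotate_days(normalize_stream(raw, "gps"),
                                    "2021-01-04"))
  stat <- g[g$speed < 0.7, ]
  cl1 <- cluster_venues(stat)
  set.seed(6)
  for (i in 1:5) {
    perm <- sample(nrow(stat))
    stat2 <- stat[perm, ][order(stat$min_of_day[perm]), ]
    cl2 <- cluster_venues(stat2)
    expect_equal(cl2$centroids, cl1$centroids, tolerance = 1e-12)
  }
})

test_that("empty input gives an empty clustering", {
  cl <- cluster_venues(NULL)
  expect_equal(nrow(cl$centroids), 0)
})

test_that("position interpolation stays at a single venue", {
  df <- data.frame(min_of_day = c(600, 606),
                   double_latitude = 34, double_longitude = -118)
  cl <- structure(list(labels = c(1L, 1L),
                       centroids = data.frame(cluster = 1L, lat = 34,
                                              lon = -118, first_visit = 600),
                       dwell_min = 20), class = "venue_clustering")
  tr <- interpolate_positions(df, cl)
  expect_equal(tr$min_of_day, c(600, 603, 606))
  expect_true(all(tr$state == 1))
})

test_that("midpoints between distant venues are labeled transit", {
  df <- data.frame(min_of_day = c(600, 660),
                   double_latitude = c(34, 34.03),
                   double_longitude = -118)
  cl <- structure(list(labels = c(1L, 2L),
                       centroids = data.frame(cluster = 1:2,
                                              lat = c(34, 34.03),
                                              lon = -118,
                                              first_visit = c(600, 660)),
                       dwell_min = c(20, 20)), class = "venue_clustering")
  tr <- interpolate_positions(df, cl)
  mid <- tr[tr$min_of_day == 630, ]
  # linear-interpolation oracle: midpoint is ~1.67 km from either venue
  expect_equal(mid$lat, 34.015, tolerance = 1e-9)
  expect_equal(mid$state, 0)
  expect_equal(tr$state[1], 1)
  expect_equal(tr$state[nrow(tr)], 2)
})

test_that("fewer than two fixes give an empty trace", {
  df <- data.frame(min_of_day = 600, double_latitude = 34,
                   double_longitude = -118)
  expect_equal(nrow(interpolate_positions(df, cluster_venues(NULL))), 0)
})

test_that("home assignment follows overnight dwell with documented tie-break", {
  cl <- structure(list(labels = NULL,
                       centroids = data.frame(cluster = 1:2, lat = c(34, 35),
                                              lon = -118,
                                              first_visit = c(10, 100)),
                       dwell_min = c(400, 100)), class = "venue_clustering")
  tr <- data.frame(min_of_day = seq(0, 477, by = 3))
  tr$state <- rep(c(1L, 2L), c(140, 20))   # 7 h at A, 1 h at B
  tr$lat <- 0; tr$lon <- 0
  expect_equal(assign_home(tr, cl), 1L)
  # equal dwell: earlier-first-visited wins
  tr2 <- data.frame(min_of_day = seq(0, 237, by = 3),
                    state = rep(c(2L, 1L), each = 40), lat = 0, lon = 0)
  expect_equal(assign_home(tr2, cl), 1L)
  # no overnight dwell
  tr3 <- data.frame(min_of_day = c(600, 603), state = c(1L, 1L),
                    lat = 0, lon = 0)
  expect_true(is.na(assign_home(tr3, cl)))
})

test_that("entropy features match hand-computed values", {
  # one venue all day
  tr1 <- data.frame(min_of_day = seq(480, 960, 3), state = 1L,
                    lat = 34, lon = -118)
  cl1 <- structure(list(centroids = data.frame(cluster = 1L, lat = 34,
                                               lon = -118, first_visit = 480),
                        dwell_min = 480), class = "venue_clustering")
  f1 <- mobility_daily_features(tr1, cl1, 1L)
  expect_equal(unname(f1["entropy"]), 0)
  expect_equal(unname(f1["norm_entropy"]), 0)
  expect_equal(unname(f1["n_locations"]), 1)

  # two venues, equal dwell -> ln 2, normalized 1
  tr2 <- data.frame(min_of_day = seq(480, 957, 3),
                    state = rep(1:2, each = 80), lat = 34, lon = -118)
  cl2 <- structure(list(centroids = data.frame(cluster = 1:2, lat = 34,
                                               lon = -118,
                                               first_visit = c(480, 720)),
                        dwell_min = c(240, 240)), class = "venue_clustering")
  f2 <- mobility_daily_features(tr2, cl2, 1L)
  expect_equal(unname(f2["entropy"]), log(2), tolerance = 1e-12)
  expect_equal(unname(f2["norm_entropy"]), 1, tolerance = 1e-12)

  # dwell shares (0.5, 0.25, 0.25) -> 1.0397 by brute force
  tr3 <- data.frame(min_of_day = seq(480, 957, 3),
                    state = rep(1:3, c(80, 40, 40)), lat = 34, lon = -118)
  cl3 <- structure(list(centroids = data.frame(cluster = 1:3, lat = 34,
                                               lon = -118,
                                               first_visit = c(1, 2, 3)),
                        dwell_min = c(240, 120, 120)),
                   class = "venue_clustering")
  f3 <- mobility_daily_features(tr3, cl3, 1L)
  expect_equal(unname(f3["entropy"]), bf_entropy(c(0.5, 0.25, 0.25)),
               tolerance = 1e-12)
  expect_equal(unname(f3["entropy"]), 1.0397, tolerance = 1e-4)
})

test_that("entropy oracle equivalence on random dwell distributions", {
  set.seed(12)
  for (i in 1:100) {
    k <- sample(1:6, 1)
    p <- as.numeric(stats::rmultinom(1, 200, runif(k) + 0.05)) / 200
    expect_equal(-sum(ifelse(p > 0, p * log(p), 0)), bf_entropy(p),
                 tolerance = 1e-12)
  }
})

test_that("daily feature invariants hold on generated days", {
  ch <- small_cohort()
  f <- cached("small_mobility", extract_cohort_features(ch, "mobility"))
  for (s in names(f)) {
    m <- f[[s]]
    nl <- m[, "n_locations"]; ent <- m[, "entropy"]
    ok <- !is.na(nl) & !is.na(ent)
    expect_true(all(ent[ok] >= -1e-9))
    expect_true(all(ent[ok] <= log(pmax(nl[ok], 1)) + 1e-9))
    ne <- m[ok, "norm_entropy"]
    expect_true(all(ne >= -1e-9 & ne <= 1 + 1e-9))
    tah <- m[, "time_at_home"]
    expect_true(all(tah[!is.na(tah)] <= 1440))
    tahn <- m[, "time_at_home_night"]
    expect_true(all(tahn[!is.na(tahn)] <= 480))
  }
})
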