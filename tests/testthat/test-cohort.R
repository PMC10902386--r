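test_that("identical seed and config give byte-identical cohorts", {
  cfg <- cohort_config(n_subjects = 2, n_days = 40, seed = 11,
                       assessment_period_days = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$gps, b$gps)
  expect_identical(a$screen, b$screen)
  expect_identical(a$comm, b$comm)
  expect_identical(a$assessments, b$assessments)
  expect_identical(a$truth$latent_mood, b$truth$latent_mood)
})

test_that("config validation rejects bad values", {
  expect_error(cohort_config(n_subjects = 0, n_days = 40, seed = 1), "n_subjects")
  expect_error(cohort_config(n_subjects = 1, n_days = 10, seed = 1), "n_days")
  expect_error(cohort_config(n_subjects = 1, n_days = 40, seed = 1,
                             dropout_hazard = 1.2), "probabilities")
  expect_error(cohort_config(n_subjects = 1, n_days = 40, seed = 1,
                             loading_mu = c(nonexistent_feature = 1)),
               "unknown feature")
  expect_error(cohort_config(n_subjects = 1, n_days = 40), "seed")
})

test_that("latent mood degenerates to the subject intercept without noise", {
  cfg <- cohort_config(n_subjects = 3, n_days = 50, seed = 5, noise_sd = 0,
                       trend_sd = 0, season_amp_sd = 0)
  truth <- simulate_truth(cfg)
  for (s in 1:3) {
    m <- simulate_latent_mood(cfg, s, truth)
    expect_equal(stats::sd(m), 0, tolerance = 1e-12)
    expect_true(m[1] >= 5 && m[1] <= 95)
  }
})

test_that("latent mood stays in [0,100] and is smooth-ish day to day", {
  cfg <- cohort_config(n_subjects = 4, n_days = 150, seed = 9)
  truth <- simulate_truth(cfg)
  expect_true(all(truth$latent_mood >= 0 & truth$latent_mood <= 100))
  step <- abs(diff(truth$latent_mood[, 1]))
  expect_lt(stats::median(step), 5)
})

test_that("zero effect heterogeneity gives identical loadings", {
  cfg <- cohort_config(n_subjects = 6, n_days = 40, seed = 3,
                       effect_heterogeneity = 0)
  truth <- simulate_truth(cfg)
  expect_true(all(apply(truth$loadings, 2, function(z) max(z) - min(z)) == 0))
  expect_equal(unname(truth$loadings[1, ]), unname(cfg$loading_mu))
})

test_that("assessment schedule, dropout and noise behave as configured", {
  cfg <- cohort_config(n_subjects = 1, n_days = 70, seed = 21,
                       assessment_period_days = 7, dropout_hazard = 0,
                       noise_sd = 0)
  truth <- simulate_truth(cfg)
  a <- simulate_assessments(cfg, truth, 1)
  expect_equal(nrow(a), 10)                       # 70 days, weekly, day 1 start
  expect_equal(a$day, seq(1, 70, by = 7))
  expect_equal(a$score, truth$latent_mood[a$day, 1])  # zero observation noise

  cfg2 <- cohort_config(n_subjects = 1, n_days = 70, seed = 21,
                        assessment_period_days = 7, dropout_hazard = 1)
  a2 <- simulate_assessments(cfg2, simulate_truth(cfg2), 1)
  expect_equal(nrow(a2), 1)                       # everyone drops after first
})

test_that("sensor_missing_rate = 1 yields empty streams", {
  cfg <- cohort_config(n_subjects = 2, n_days = 35, seed = 8,
                       sensor_missing_rate = 1)
  ch <- simulate_cohort(cfg)
  expect_equal(nrow(ch$gps), 0)
  expect_equal(nrow(ch$screen), 0)
  expect_equal(nrow(ch$comm), 0)
})

test_that("generated events carry cohort subjects and in-range timestamps", {
  ch <- small_cohort()
  cfg <- ch$config
  ids <- sprintf("S%03d", seq_len(cfg$n_subjects))
  t0 <- as.numeric(as.POSIXct(paste(cfg$origin_date, "00:00:00"),
                              tz = cfg$tz))
  t1 <- t0 + (cfg$n_days + 1) * 86400 + 7200
  for (stream in list(ch$gps, ch$screen, ch$comm)) {
    expect_true(all(stream$subject %in% ids))
    expect_true(all(stream$timestamp / 1000 >= t0))
    expect_true(all(stream$timestamp / 1000 <= t1))
  }
})

test_that("per-stream draws are independent of which streams are requested", {
  cfg <- cohort_config(n_subjects = 2, n_days = 40, seed = 13)
  full <- simulate_cohort(cfg)
  reduced <- simulate_cohort(cfg, streams = c("screen", "comm"))
  expect_identical(full$screen, reduced$screen)
  expect_identical(full$comm, reduced$comm)
  expect_equal(nrow(reduced$gps), 0)
})

test_that("a zero planted loading leaves the feature uncoupled from mood", {
  cfg <- cohort_config(n_subjects = 1, n_days = 200, seed = 31,
                       assessment_period_days = 7, sensor_missing_rate = 0,
                       effect_heterogeneity = 0,
                       loading_mu = c(time_at_home = 0, sleep_duration = -35))
  ch <- simulate_cohort(cfg)
  feats <- extract_cohort_features(ch)[[1]]
  lat <- ch$truth$latent_mood[, 1]
  rho <- stats::cor(lat, feats[, "time_at_home"], use = "complete.obs")
  expect_lt(abs(rho), 0.1)
})

test_that("a negative loading on venue count shows up in the data", {
  cfg <- cohort_config(n_subjects = 1, n_days = 200, seed = 32,
                       assessment_period_days = 7, sensor_missing_rate = 0,
                       effect_heterogeneity = 0,
                       loading_mu = c(n_locations = -0.8))
  ch <- simulate_cohort(cfg)
  feats <- extract_cohort_features(ch, "mobility")[[1]]
  lat <- ch$truth$latent_mood[, 1]
  rho <- stats::cor(lat, feats[, "n_locations"], use = "complete.obs")
  expect_lt(rho, 0)
})

test_that("a YAML file configures a cohort", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 3", "n_days: 45", "seed: 12",
               "assessment_period_days: 7", "noise_sd: 2.5",
               "loading_mu:", "  time_at_home: 0.4"), path)
  cfg <- cohort_config_from_yaml(path)
  expect_equal(cfg$n_subjects, 3L)
  expect_equal(cfg$noise_sd, 2.5)
  expect_equal(unname(cfg$loading_mu["time_at_home"]), 0.4)
  unlink(path)
})

test_that("the recovery cohort plants one exercised loading per subject", {
  rec <- cached("recovery_cohort_small", simulate_recovery_cohort(
    n_subjects = 5, n_days = 60, seed = 55, sensor_missing_rate = 0))
  lo <- rec$cohort$truth$loadings
  expect_true(all(rowSums(lo != 0) == 1))
  for (s in 1:5) {
    expect_equal(colnames(lo)[which(lo[s, ] != 0)], rec$planted$feature[s])
    expect_equal(sign(lo[s, rec$planted$feature[s]]), rec$planted$sign[s])
    # severity genuinely varies for every subject
    expect_gt(stats::sd(rec$cohort$truth$latent_mood[, s]), 5)
  }
})

test_that("cohort CSVs round-trip through the sensor readers", {
  ch <- small_cohort()
  dir <- tempfile("cohort")
  write_cohort_csv(ch, dir)
  gps <- read_sensor_csv(file.path(dir, "gps.csv"), "gps", ch$config$tz)
  expect_s3_class(gps, "event_stream")
  expect_equal(nrow(gps), nrow(unique(ch$gps)))
  lat <- utils::read.csv(file.path(dir, "truth_latent.csv"),
                         check.names = FALSE)
  expect_equal(as.numeric(lat[["S001"]]), ch$truth$latent_mood[, "S001"])
  unlink(dir, recursive = TRUE)
})
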