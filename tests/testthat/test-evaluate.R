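test_that("MAPE matches its worked examples and the epsilon guard", {
  expect_equal(mape(c(50, 60), c(50, 60)), 0)
  expect_equal(mape(c(100, 50), c(90, 55)), 10)       # mean(0.10, 0.10)
  expect_equal(mape(0, 5), 500)                        # o = 0 guarded by eps 1
  expect_true(is.na(mape(c(NA, NA), c(1, 2))))
  expect_equal(mape(c(10, NA), c(11, 5)), 10)          # missing pair dropped
})

test_that("MAPE equals a brute-force implementation on random vectors", {
  set.seed(27)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    o <- runif(n, 0, 100); p <- runif(n, 0, 100)
    p[sample(n, 1)] <- NA
    expect_equal(mape(o, p), bf_mape(o, p), tolerance = 1e-12)
  }
})

test_that("accuracy tests: identity, anticorrelation, and degenerate input", {
  o <- c(10, 30, 50, 70, 90)
  at <- accuracy_tests(o, o)
  expect_equal(at$r, 1)
  expect_equal(at$r2, 100)
  at2 <- accuracy_tests(o, -o)
  expect_gte(at2$p_r, 0.5)
  at3 <- accuracy_tests(o, rep(5, 5))
  expect_true(at3$degenerate)
  expect_true(is.na(accuracy_tests(o[1:2], o[1:2])$r))
})

test_that("Pearson R and one-sided p match the closed-form oracle", {
  set.seed(28)
  for (i in 1:100) {
    n <- sample(5:20, 1)
    o <- rnorm(n); p <- rnorm(n) + 0.5 * o
    at <- accuracy_tests(o, p)
    bf <- bf_pearson(o, p)
    expect_equal(at$r, bf$r, tolerance = 1e-10)
    expect_equal(at$p_r, bf$p_one_sided, tolerance = 1e-10)
    expect_equal(at$r2, 100 * bf$r^2, tolerance = 1e-8)
  }
})

test_that("BH step-up matches hand computation and the brute-force oracle", {
  out <- bh_fdr(c(0.01, 0.02, 0.04))
  expect_true(all(out$significant))                 # p(3)=0.04 <= 0.05
  expect_false(any(bh_fdr(rep(1, 5))$significant))
  expect_true(bh_fdr(0.04)$significant)             # m = 1: raw threshold
  set.seed(29)
  for (i in 1:100) {
    m <- sample(3:25, 1)
    p <- runif(m)^sample(1:3, 1)
    expect_equal(unname(bh_fdr(p)$significant), bf_bh_reject(p))
  }
})

test_that("significance additionally requires a positive correlation", {
  out <- bh_fdr(c(0.001, 0.001), r = c(0.9, -0.9))
  expect_equal(unname(out$significant), c(TRUE, FALSE))
})

test_that("the horizon curve bins pairs and is internally consistent", {
  set.seed(30)
  n <- 60
  obs <- runif(n, 20, 80)
  pr <- data.frame(value = obs + rnorm(n, 0, 8),
                   weeks_ahead = rep(1:3, each = 20))
  hc <- horizon_curve(pr, obs, n_boot = 100, seed = 1)
  expect_equal(hc$weeks_ahead, 1:3)
  for (w in 1:3) {
    idx <- pr$weeks_ahead == w
    expect_equal(hc$r2[hc$weeks_ahead == w],
                 accuracy_tests(obs[idx], pr$value[idx])$r2)
  }
  expect_true(all(hc$lo <= hc$r2 + 1e-9 & hc$r2 <= hc$hi + 1e-9))
  # single-bin case and small-bin suppression
  hc2 <- horizon_curve(pr[1:20, ], obs[1:20], n_boot = 50, seed = 1)
  expect_equal(nrow(hc2), 1)
  hc3 <- horizon_curve(pr[1:5, ], obs[1:5], n_boot = 10, seed = 1)
  expect_equal(nrow(hc3), 0)
})

test_that("log2 fold changes follow the published interpretation", {
  expect_equal(unname(fold_change_vs_baseline(list(mape = 20),
                                              list(mape = 20))["log2_mape"]),
               0)
  # baseline error twice the feature model's -> -1
  expect_equal(unname(fold_change_vs_baseline(list(mape = 10),
                                              list(mape = 20))["log2_mape"]),
               -1)
  expect_equal(unname(fold_change_vs_baseline(list(mape = 40),
                                              list(mape = 10))["log2_mape"]),
               2)
  fc <- fold_change_vs_baseline(list(mape = 10, r2 = 60),
                                list(mape = 20, r2 = 30))
  expect_equal(unname(fc["log2_r2"]), 1)
  expect_true(is.na(fold_change_vs_baseline(list(mape = 1),
                                            list(mape = 0))["log2_mape"]))
})

test_that("top predictors apply the odds-ratio band and rank by effect", {
  mk_model <- function(cf) {
    structure(list(coef = cf, family = "logistic", mode = "idiographic"),
              class = "mood_enet")
  }
  models <- list(
    A = mk_model(c("(Intercept)" = 0.2, f_small = log(1.04),
                   f_in = log(1.06), f_big = log(0.8))),
    B = mk_model(c("(Intercept)" = 0, study_day = log(0.9))))
  tp <- top_predictors(models)
  a <- tp$per_subject[tp$per_subject$subject == "A", ]
  expect_equal(sort(a$feature), c("f_big", "f_in"))
  expect_equal(a$feature[a$rank == 1], "f_big")
  expect_false("f_small" %in% tp$per_subject$feature)
  b <- tp$per_subject[tp$per_subject$subject == "B", ]
  expect_equal(b$feature, "study_day")   # day-only model: day-only report
})

test_that("variance partition recovers known simulated components", {
  set.seed(31)
  n_subj <- 150; n_obs <- 10
  subj <- rep(sprintf("P%03d", seq_len(n_subj)), each = n_obs)
  re <- rep(rnorm(n_subj, 0, 2), each = n_obs)       # subject variance 4
  d <- data.frame(subject = subj, score = 50 + re + rnorm(n_subj * n_obs))
  vp <- variance_partition(d, random = "subject")
  expect_equal(vp$fraction[vp$component == "subject"], 0.8, tolerance = 0.05)
  expect_equal(sum(vp$fraction), 1, tolerance = 1e-6)

  # null case: no subject effect simulated
  d0 <- data.frame(subject = subj, score = rnorm(n_subj * n_obs, 50))
  vp0 <- variance_partition(d0, random = "subject")
  expect_lt(vp0$fraction[vp0$component == "subject"], 0.03)
})

test_that("variance partition handles fixed effects via the post-hoc rule", {
  set.seed(32)
  n_subj <- 80; n_obs <- 12
  subj <- rep(seq_len(n_subj), each = n_obs)
  day <- rep(seq_len(n_obs), n_subj)
  re <- rnorm(n_subj, 0, 2)
  score <- 40 + rep(re, each = n_obs) + 0.9 * day + rnorm(n_subj * n_obs)
  d <- data.frame(subject = subj, day = day, score = score)
  vp <- variance_partition(d, random = "subject", fixed = "day")
  # post-hoc rule: var(X beta) for the day slope against the realized
  # subject-intercept and residual variances
  f_day <- vp$fraction[vp$component == "day"]
  exp_day <- 0.81 * stats::var(day) /
    (stats::var(re) + 0.81 * stats::var(day) + 1)
  expect_equal(f_day, exp_day, tolerance = 0.05)
  expect_equal(sum(vp$fraction), 1, tolerance = 1e-6)
  # bootstrap CIs bracket the point estimate
  vp2 <- variance_partition(d[d$subject <= 40, ], random = "subject",
                            fixed = "day", n_boot = 20, seed = 4)
  expect_true(all(vp2$lo <= vp2$fraction + 1e-9 &
                  vp2$fraction <= vp2$hi + 1e-9))
})
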