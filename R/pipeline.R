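#' End-to-end mood-prediction pipeline
#'
#' Runs the whole analysis on a cohort: normalize raw streams, extract daily
#' behavioral features, expand/impute/standardize them per subject with
#' training-only fitting, interpolate assessments into daily latent traits,
#' fit baseline / nomothetic / modified-nomothetic / idiographic elastic
#' nets, predict the held-out 30% of each trajectory, and score the
#' predictions at the group and individual level.
#'
#' @name pipeline
NULL

#' Daily base features for every subject of a cohort
#'
#' @param cohort a [simulate_cohort()] result (or a list with raw `gps`,
#'   `screen`, `comm` data frames plus `config`).
#' @param groups which feature groups to extract: `"mobility"` (GPS) and/or
#'   `"rhythm_social"` (screen + communication).
#' @return named list per subject of day x feature matrices.
#' @export
extract_cohort_features <- function(cohort,
                                    groups = c("mobility", "rhythm_social")) {
  config <- cohort$config
  ids <- subject_ids(config)
  tz <- config$tz
  nd <- config$n_days
  streams <- list()
  if ("mobility" %in% groups)
    streams$gps <- normalize_stream(cohort$gps, "gps", tz)
  if ("rhythm_social" %in% groups) {
    streams$screen <- normalize_stream(cohort$screen, "screen", tz)
    streams$comm <- normalize_stream(cohort$comm, "comm", tz)
  }
  by_subj <- lapply(streams, function(s) split(s, factor(s$subject, ids)))
  android <- if (!is.null(cohort$truth))
    cohort$truth$android else stats::setNames(rep(TRUE, length(ids)), ids)
  out <- lapply(ids, function(id) {
    parts <- list()
    if ("mobility" %in% groups) {
      g <- by_subj$gps[[id]]
      attr(g, "tz") <- tz
      parts$mob <- mobility_features(g, config$origin_date, nd)
    }
    if ("rhythm_social" %in% groups) {
      s <- by_subj$screen[[id]]; cm <- by_subj$comm[[id]]
      attr(s, "tz") <- tz; attr(cm, "tz") <- tz
      parts$rs <- rhythm_social_features(s, cm, config$origin_date, nd,
                                         android = android[[id]])
    }
    m <- do.call(cbind, lapply(parts, function(p)
      as.matrix(p[, setdiff(names(p), "day"), drop = FALSE])))
    rownames(m) <- NULL
    m
  })
  names(out) <- ids
  out
}

#' Run the full prediction pipeline on a cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @param latent_method latent trait used as the response and evaluation
#'   target: `"locf"`, `"cs4"`, `"cs24"`, `"cscv"`, or `"none"`.
#' @param family `"logistic"` or `"linear"` elastic net.
#' @param modes model modes to fit.
#' @param groups feature groups to extract.
#' @param expand expand daily features with rolling statistics/contrasts.
#' @param ratios include ratio contrasts in the expansion.
#' @param eval_target `"obs_days"` scores predictions at test-set assessment
#'   days against the full-series latent value there (for LOCF this is the
#'   raw observed score); `"all_days"` scores every test day.
#' @param min_assessments,min_sensor_days,min_test eligibility filters:
#'   assessments per subject, sensor days inside the assessment span, and
#'   test assessments needed for an individual-level record.
#' @param blocked_folds use contiguous time-block CV folds (see
#'   [mood_enet()]).
#' @param seed seed for CV folds (random-fold mode) and bootstrap.
#' @param features optional precomputed [extract_cohort_features()] output.
#' @param keep_features retain the per-subject design matrices in the result.
#' @return object of class `mood_pipeline`.
#' @export
run_pipeline <- function(cohort,
                         latent_method = "cs24",
                         family = "logistic",
                         modes = c("baseline", "nomothetic",
                                   "nomothetic_star", "idiographic"),
                         groups = c("mobility", "rhythm_social"),
                         expand = TRUE, ratios = TRUE,
                         eval_target = c("obs_days", "all_days"),
                         min_assessments = 5L, min_sensor_days = 60L,
                         min_test = 5L,
                         blocked_folds = TRUE, seed = 1L,
                         features = NULL, keep_features = FALSE,
                         verbose = FALSE) {
  eval_target <- match.arg(eval_target)
  t_start <- Sys.time()
  say <- function(...) if (verbose)
    message(sprintf("[%5.0fs] ", difftime(Sys.time(), t_start,
                                          units = "secs")), ...)
  config <- cohort$config
  ids <- subject_ids(config)
  if (is.null(features)) {
    say("extracting daily features for ", length(ids), " subjects")
    features <- extract_cohort_features(cohort, groups)
  }
  say("preparing per-subject designs")

  subjects <- list()
  excluded <- data.frame(subject = character(0), reason = character(0))
  for (id in ids) {
    ass <- cohort$assessments[cohort$assessments$subject == id, , drop = FALSE]
    daily <- features[[id]]
    res <- tryCatch({
      if (nrow(ass) < min_assessments)
        stop("fewer than ", min_assessments, " assessments")
      span <- seq(min(ass$day), max(ass$day))
      n_sensor <- sum(rowSums(!is.na(daily[span, , drop = FALSE])) > 0)
      if (n_sensor < min_sensor_days)
        stop("fewer than ", min_sensor_days, " sensor days in span")
      split <- make_split(ass, min_assessments = min_assessments)
      prep <- prepare_features(daily, seq_len(split$split_day),
                               expand = expand, ratios = ratios)
      # study day, standardized with training statistics like the features
      day_raw <- seq_len(nrow(daily))
      mu_d <- mean(day_raw[seq_len(split$split_day)])
      sd_d <- stats::sd(day_raw[seq_len(split$split_day)])
      x <- cbind(prep$x, study_day = (day_raw - mu_d) / sd_d)
      lat_train <- latent_series(ass, latent_method, "train_only",
                                 split$split_day)
      lat_full <- latent_series(ass, latent_method, "full_series",
                                split$split_day)
      train_days <- lat_train$day
      test_days <- if (eval_target == "obs_days") split$test_days else
        seq(split$split_day + 1L, max(ass$day))
      obs_val <- lat_full$value[match(test_days, lat_full$day)]
      if (latent_method == "none") {
        train_days <- intersect(train_days, ass$day)
        obs_val <- ass$score[match(test_days, ass$day)]
      }
      list(id = id, assessments = ass, split = split, prep = prep, x = x,
           y_train = lat_train$value[match(train_days, lat_train$day)],
           train_days = train_days, test_days = test_days,
           observed = obs_val)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      excluded <- rbind(excluded, data.frame(subject = id, reason = res))
    } else subjects[[id]] <- res
  }
  if (!length(subjects))
    stop("run_pipeline: no eligible subjects")

  sx <- function(s, days) s$x[days, , drop = FALSE]
  common_cols <- Reduce(intersect, lapply(subjects, function(s) colnames(s$x)))

  models <- list(); predictions <- list()
  for (mode in modes) {
    say("fitting mode: ", mode)
    if (mode %in% c("baseline", "idiographic")) {
      fits <- list(); preds <- list()
      for (s in subjects) {
        f <- mood_enet(sx(s, s$train_days), s$y_train,
                       subject = rep(s$id, length(s$train_days)),
                       family = family, mode = mode,
                       blocked_folds = blocked_folds, seed = seed)
        p <- stats::predict(f, sx(s, s$test_days),
                            subject = rep(s$id, length(s$test_days)),
                            days = s$test_days,
                            last_train_obs_day = s$split$split_day)
        p$observed <- s$observed
        fits[[s$id]] <- f; preds[[s$id]] <- p
      }
      models[[mode]] <- fits
      predictions[[mode]] <- do.call(rbind, preds)
    } else {
      xtr <- do.call(rbind, lapply(subjects, function(s)
        sx(s, s$train_days)[, common_cols, drop = FALSE]))
      ytr <- unlist(lapply(subjects, function(s) s$y_train))
      str_ <- unlist(lapply(subjects, function(s)
        rep(s$id, length(s$train_days))))
      f <- mood_enet(xtr, ytr, subject = str_, family = family, mode = mode,
                     blocked_folds = blocked_folds, seed = seed)
      preds <- lapply(subjects, function(s) {
        p <- stats::predict(f,
                            sx(s, s$test_days)[, common_cols, drop = FALSE],
                            subject = rep(s$id, length(s$test_days)),
                            days = s$test_days,
                            last_train_obs_day = s$split$split_day)
        p$observed <- s$observed
        p
      })
      models[[mode]] <- f
      predictions[[mode]] <- do.call(rbind, preds)
    }
  }

  say("scoring predictions")
  evaluation <- evaluate_predictions(predictions, min_test = min_test,
                                     seed = seed)
  say("done")
  out <- list(config = config, excluded = excluded,
              subjects = names(subjects),
              splits = lapply(subjects, `[[`, "split"),
              models = models, predictions = predictions,
              evaluation = evaluation,
              latent_method = latent_method, family = family,
              eval_target = eval_target)
  if (keep_features) out$features <- lapply(subjects, `[[`, "x")
  out$imputation <- lapply(subjects, function(s) s$prep$model)
  out$scale_stats <- lapply(subjects, function(s) s$prep$scale)
  out$y_train <- lapply(subjects, `[[`, "y_train")
  class(out) <- "mood_pipeline"
  out
}

#' Score a set of per-mode predictions
#'
#' @param predictions named list (per mode) of data frames with `subject`,
#'   `value`, `observed`, `weeks_ahead`.
#' @param min_test minimum valid test assessments for an individual record.
#' @param q FDR level across subjects.
#' @param seed bootstrap seed for the horizon curve.
#' @return list `group` (one row per mode), `individual` (one row per mode
#'   and eligible subject, with BH q-values), `horizon` (per-mode horizon
#'   curves), `fold_change` (per-subject log2 MAPE fold change of each
#'   feature-based mode over the baseline, when baseline was fitted).
#' @export
evaluate_predictions <- function(predictions, min_test = 5L, q = 0.05,
                                 seed = 1L) {
  group <- do.call(rbind, lapply(names(predictions), function(mode) {
    pr <- predictions[[mode]]
    at <- accuracy_tests(pr$observed, pr$value)
    data.frame(mode = mode, mape = mape(pr$observed, pr$value),
               r = at$r, r2 = at$r2, p_r = at$p_r, p_lrt = at$p_lrt,
               n = at$n)
  }))
  individual <- do.call(rbind, lapply(names(predictions), function(mode) {
    pr <- predictions[[mode]]
    rows <- lapply(split(pr, pr$subject), function(d) {
      n_valid <- sum(!is.na(d$value) & !is.na(d$observed))
      if (n_valid < min_test) return(NULL)
      at <- accuracy_tests(d$observed, d$value)
      data.frame(mode = mode, subject = d$subject[1],
                 mape = mape(d$observed, d$value), r = at$r, r2 = at$r2,
                 p_r = at$p_r, n = at$n)
    })
    out <- do.call(rbind, rows)
    if (!is.null(out) && nrow(out)) {
      fdr <- bh_fdr(out$p_r, q = q, r = out$r)
      out$q <- fdr$q_values
      out$significant <- fdr$significant
    }
    out
  }))
  horizon <- lapply(predictions, function(pr)
    horizon_curve(pr, pr$observed, seed = seed))
  fold_change <- NULL
  if ("baseline" %in% names(predictions) && !is.null(individual)) {
    base <- individual[individual$mode == "baseline", ]
    fc_rows <- lapply(setdiff(unique(individual$mode), "baseline"),
                      function(mode) {
      feat <- individual[individual$mode == mode, ]
      common <- intersect(feat$subject, base$subject)
      if (!length(common)) return(NULL)
      data.frame(mode = mode, subject = common,
                 log2_mape = log2(feat$mape[match(common, feat$subject)] /
                                  base$mape[match(common, base$subject)]))
    })
    fold_change <- do.call(rbind, fc_rows)
  }
  list(group = group, individual = individual, horizon = horizon,
       fold_change = fold_change)
}

#' @export
print.mood_pipeline <- function(x, ...) {
  cat("mood_pipeline: ", length(x$subjects), " subjects (",
      nrow(x$excluded), " excluded), latent = ", x$latent_method,
      ", family = ", x$family, "\n", sep = "")
  g <- x$evaluation$group
  if (!is.null(g)) {
    cat("group-level accuracy:\n")
    print(data.frame(mode = g$mode, MAPE = round(g$mape, 1),
                     R2 = round(g$r2, 1)), row.names = FALSE)
  }
  invisible(x)
}
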