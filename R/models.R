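#' Elastic-net models of future mood
#'
#' Baseline (intercept + study day), nomothetic (one pooled model),
#' modified-nomothetic (pooled model with unpenalized per-subject
#' intercepts), and idiographic (one model per subject) elastic nets predict
#' the daily latent trait from standardized features plus study day. The
#' mixing parameter is fixed at alpha = 0.5 and the shrinkage lambda is
#' chosen by 10-fold cross-validation. The "logistic" family treats
#' score/100 as a fractional response under binomial deviance so predictions
#' stay inside the severity scale; the linear family may leave [0,100], and
#' such predictions are recorded as missing.
#'
#' @name mood_models
NULL

#' Train/test split of a subject's trajectory
#'
#' The training set is the first `floor(frac * n)` assessments (at least 4,
#' so a spline can be interpolated); the split day is the day of the last of
#' these, and test days are everything after.
#'
#' @param series assessment data frame (`day`, `score`) for one subject.
#' @param frac training fraction of the assessment count (default 0.7).
#' @param min_assessments subjects with fewer assessments are rejected.
#' @return list of class `split_spec`: `split_day`, `train_days`,
#'   `test_days` (assessment days each side), `n_train`, `n_test`.
#' @export
make_split <- function(series, frac = 0.7, min_assessments = 5L) {
  n <- nrow(series)
  if (n < min_assessments)
    stop("make_split: fewer than ", min_assessments, " assessments")
  n_train <- max(4L, as.integer(floor(frac * n + 1e-9)))
  if (n_train >= n) stop("make_split: no assessments left for testing")
  train_days <- series$day[seq_len(n_train)]
  if (stats::sd(series$score[seq_len(n_train)]) == 0 ||
      length(unique(series$score[seq_len(n_train)])) < 2)
    stop("make_split: no variation in training-set scores; subject excluded")
  structure(list(split_day = train_days[n_train],
                 train_days = train_days,
                 test_days = series$day[(n_train + 1L):n],
                 n_train = n_train, n_test = n - n_train),
            class = "split_spec")
}

model_family <- function(family) {
  switch(family,
         logistic = stats::quasibinomial(),
         linear = stats::gaussian())
}

# contiguous time-block folds within each subject's training rows
blocked_foldid <- function(subject, nfolds) {
  fid <- integer(length(subject))
  for (s in unique(subject)) {
    i <- which(subject == s)
    fid[i] <- as.integer(cut(seq_along(i), breaks = nfolds, labels = FALSE))
  }
  fid
}

#' Fit a mood elastic-net model
#'
#' @param x numeric matrix of standardized features for the training days;
#'   must contain a `study_day` column. Ignored (except `study_day`) for
#'   `mode = "baseline"`.
#' @param y latent trait on the same days, in `[0,100]`.
#' @param subject subject id per row (needed for pooled modes).
#' @param family `"logistic"` (fractional-response binomial on y/100,
#'   predictions via 100 * sigmoid) or `"linear"`.
#' @param mode `"baseline"`, `"nomothetic"`, `"nomothetic_star"` or
#'   `"idiographic"` (for idiographic fits call once per subject).
#' @param nfolds cross-validation folds for lambda (reduced with a message
#'   when training rows are scarce).
#' @param seed integer seed recorded in the model and used for random folds.
#' @param blocked_folds use contiguous time-block folds (default TRUE,
#'   respecting serial correlation); FALSE uses seeded random folds.
#' @return object of class `mood_enet`.
#' @export
mood_enet <- function(x, y, subject = NULL,
                      family = c("logistic", "linear"),
                      mode = c("idiographic", "nomothetic",
                               "nomothetic_star", "baseline"),
                      nfolds = 10L, seed = 1L, blocked_folds = TRUE) {
  family <- match.arg(family)
  mode <- match.arg(mode)
  stopifnot(is.matrix(x), "study_day" %in% colnames(x),
            length(y) == nrow(x))
  if (stats::sd(y) == 0)
    stop("mood_enet: response has zero variance in the training set")
  if (is.null(subject)) subject <- rep("all", nrow(x))
  fam <- model_family(family)
  yy <- if (family == "logistic") pmin(1, pmax(0, y / 100)) else y

  if (mode == "baseline") {
    df <- data.frame(yy = yy, study_day = x[, "study_day"])
    fit <- stats::glm(yy ~ study_day, family = fam, data = df)
    obj <- list(family = family, mode = mode, alpha = 0.5, lambda = NA_real_,
                fit = fit, coef = stats::coef(fit), seed = seed,
                features = "study_day")
    class(obj) <- "mood_enet"
    return(obj)
  }

  xx <- x
  pen <- rep(1, ncol(xx))
  if (mode == "nomothetic_star") {
    subs <- sort(unique(subject))
    ind <- sapply(subs, function(s) as.numeric(subject == s))
    colnames(ind) <- paste0("subj_", subs)
    xx <- cbind(xx, ind)
    pen <- c(pen, rep(0, length(subs)))   # unpenalized intercept shifts
  }
  # scarce training rows: shrink the fold count so folds keep >= 3 rows
  nfolds <- min(nfolds, max(3L, nrow(xx) %/% 3L))
  if (blocked_folds) {
    foldid <- blocked_foldid(subject, nfolds)
  } else {
    set.seed(seed)
    foldid <- sample(rep(seq_len(nfolds), length.out = nrow(xx)))
  }
  # the logistic family runs on glmnet's native binomial path, which
  # accepts a two-column matrix of proportions as a fractional response
  if (family == "logistic") {
    yfit <- cbind(1 - yy, yy)
    fam_arg <- "binomial"
  } else {
    yfit <- yy
    fam_arg <- "gaussian"
  }
  # the path stops at 1% of lambda_max: with strong column correlation the
  # unbounded default path spends most of its time on near-saturated fits
  # the CV curve never selects
  cv <- glmnet::cv.glmnet(xx, yfit, family = fam_arg, alpha = 0.5,
                          foldid = foldid, penalty.factor = pen,
                          type.measure = "deviance", standardize = FALSE,
                          nlambda = 100, lambda.min.ratio = 0.01)
  cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[, 1]
  obj <- list(family = family, mode = mode, alpha = 0.5,
              lambda = cv$lambda.min, fit = cv, coef = cf, seed = seed,
              features = colnames(xx), blocked_folds = blocked_folds,
              subjects = sort(unique(subject)))
  class(obj) <- "mood_enet"
  obj
}

#' @export
print.mood_enet <- function(x, ...) {
  nz <- sum(x$coef[setdiff(names(x$coef), "(Intercept)")] != 0)
  cat("mood_enet: ", x$mode, " ", x$family, " elastic net (alpha = ",
      x$alpha, ")\n", sep = "")
  if (!is.na(x$lambda))
    cat("  lambda (10-fold CV): ", signif(x$lambda, 4), "\n", sep = "")
  cat("  non-zero coefficients: ", nz, " of ", length(x$features),
      "\n", sep = "")
  invisible(x)
}

#' Coefficients of a mood model
#'
#' @param object a `mood_enet`.
#' @param odds_ratio report `exp(beta)` (odds ratios; logistic family only).
#' @param ... unused.
#' @export
coef.mood_enet <- function(object, odds_ratio = FALSE, ...) {
  cf <- object$coef
  if (odds_ratio) {
    if (object$family != "logistic")
      stop("odds ratios are defined for the logistic family")
    cf <- exp(cf)
  }
  cf
}

#' @export
summary.mood_enet <- function(object, ...) {
  cf <- object$coef[names(object$coef) != "(Intercept)"]
  nz <- cf[cf != 0]
  cat("mood_enet ", object$mode, "/", object$family, ": ",
      length(nz), " active terms\n", sep = "")
  top <- utils::head(nz[order(-abs(nz))], 10)
  if (length(top)) print(signif(top, 3))
  invisible(list(active = nz))
}

#' Predict future mood on test days
#'
#' @param object a `mood_enet`.
#' @param newx feature matrix for the prediction days (same columns the
#'   model was fitted on; subject indicators are reconstructed from
#'   `subject` for the modified-nomothetic model).
#' @param subject subject ids per row (pooled modes).
#' @param days study days per row.
#' @param last_train_obs_day day of the last assessment the model trained
#'   on, used for the weeks-ahead horizon.
#' @param ... unused.
#' @return data frame `subject`, `day`, `value` (NA when a linear-family
#'   prediction leaves `[0,100]`), `weeks_ahead`.
#' @export
predict.mood_enet <- function(object, newx, subject = NULL, days = NULL,
                              last_train_obs_day = NULL, ...) {
  stopifnot(is.matrix(newx))
  if (is.null(days)) days <- newx[, "study_day"]
  if (is.null(subject)) subject <- rep("all", nrow(newx))
  if (object$mode == "idiographic" && !is.null(object$subjects) &&
      !identical(object$subjects, "all") &&
      !all(subject %in% object$subjects))
    stop("predict.mood_enet: subject(s) unseen by this idiographic model")
  if (object$mode == "baseline") {
    eta <- stats::predict(object$fit,
                          data.frame(study_day = newx[, "study_day"]),
                          type = "response")
    raw <- as.numeric(eta)
  } else {
    xx <- newx
    if (object$mode == "nomothetic_star") {
      ind_names <- grep("^subj_", object$features, value = TRUE)
      ind <- sapply(ind_names, function(nm)
        as.numeric(paste0("subj_", subject) == nm))
      ind <- matrix(ind, nrow = nrow(newx),
                    dimnames = list(NULL, ind_names))
      unseen <- !paste0("subj_", subject) %in% ind_names
      if (any(unseen))
        stop("predict.mood_enet: subject(s) unseen during fitting")
      xx <- cbind(xx, ind)
    }
    xx <- xx[, object$features, drop = FALSE]
    raw <- as.numeric(stats::predict(object$fit, newx = xx,
                                     s = "lambda.min", type = "response"))
  }
  value <- if (object$family == "logistic") 100 * raw else raw
  value[value < 0 | value > 100] <- NA_real_
  weeks <- if (is.null(last_train_obs_day)) NA_real_ else
    ceiling((days - last_train_obs_day) / 7)
  data.frame(subject = subject, day = days, value = value,
             weeks_ahead = weeks)
}
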