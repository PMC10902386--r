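#' Daily latent depression traits from sparse assessments
#'
#' Sparse CAT-DI observations are interpolated onto a daily grid either by
#' last-observation-carried-forward (LOCF) or by cubic smoothing splines
#' whose flexibility is set through the effective degrees of freedom: fixed
#' at 4 (one per severity category), equal to the number of severity
#' categories observed in the training split (2-4), or selected by
#' leave-one-out cross-validation. Train-only fits never see observations
#' after the split day; full-series fits are the evaluation targets.
#'
#' @name latent_trait
NULL

SEVERITY_BREAKS <- c(0, 35, 65, 75, 100.000001)
SEVERITY_LABELS <- c("normal", "mild", "moderate", "severe")

#' Severity category of a CAT-DI score
#'
#' normal `[0,35)`, mild `[35,65)`, moderate `[65,75)`, severe `[75,100]`.
#'
#' @param score numeric in `[0,100]`.
#' @return factor with the four severity levels.
#' @export
severity_category <- function(score) {
  cut(score, SEVERITY_BREAKS, SEVERITY_LABELS, right = FALSE)
}

in_scope <- function(series, scope, split_day) {
  if (scope == "train_only") {
    if (is.null(split_day))
      stop("train_only scope needs a split_day")
    series[series$day <= split_day, , drop = FALSE]
  } else series
}

#' LOCF interpolation
#'
#' Each day from the first to the last in-scope observation takes the most
#' recent observed score at or before it.
#'
#' @param series data frame with `day`, `score` (one subject, days strictly
#'   increasing).
#' @param scope `"full_series"` or `"train_only"`.
#' @param split_day last training day (required for `train_only`).
#' @return data frame `day`, `value`, plus method metadata columns.
#' @export
interpolate_locf <- function(series, scope = c("full_series", "train_only"),
                             split_day = NULL) {
  scope <- match.arg(scope)
  s <- in_scope(series, scope, split_day)
  if (nrow(s) < 1) stop("interpolate_locf: no observations in scope")
  days <- seq(min(s$day), max(s$day))
  vals <- if (nrow(s) == 1) rep(s$score, length(days)) else
    stats::stepfun(s$day[-1], s$score)(days)
  data.frame(day = days, value = vals, method = "locf", df_used = NA_real_,
             scope = scope)
}

#' Cubic smoothing spline latent trait
#'
#' Penalized cubic smoothing spline (via [stats::smooth.spline()]) whose
#' smoothing parameter is solved so the effective degrees of freedom (trace
#' of the smoother matrix) match `df`; evaluated on the daily grid and
#' clipped to `[0,100]`.
#'
#' @inheritParams interpolate_locf
#' @param df requested effective degrees of freedom (>= 2; must be below the
#'   number of in-scope observations).
#' @return data frame `day`, `value`, `method`, `df_used`, `scope`; the fit
#'   itself is kept in attribute `fit`.
#' @export
fit_smoothing_spline <- function(series, df,
                                 scope = c("full_series", "train_only"),
                                 split_day = NULL) {
  scope <- match.arg(scope)
  s <- in_scope(series, scope, split_day)
  n <- length(unique(s$day))
  if (df < 2) stop("fit_smoothing_spline: df must be >= 2")
  if (n <= df || n < 4)
    stop("fit_smoothing_spline: too few observations for df = ", df,
         "; fall back to LOCF")
  fit <- stats::smooth.spline(s$day, s$score, df = df, cv = FALSE,
                              all.knots = TRUE,
                              control.spar = list(tol = 1e-10, eps = 1e-11))
  days <- seq(min(s$day), max(s$day))
  vals <- pmin(100, pmax(0, stats::predict(fit, days)$y))
  out <- data.frame(day = days, value = vals, method = "cs",
                    df_used = fit$df, scope = scope)
  attr(out, "fit") <- fit
  out
}

#' Degrees of freedom from observed severity categories
#'
#' The number of distinct severity categories among the training
#' observations, clamped to `[2, 4]`.
#'
#' @param series_train training-split observations (`day`, `score`).
#' @return integer df in 2..4.
#' @export
df_from_categories <- function(series_train) {
  k <- length(unique(as.character(severity_category(series_train$score))))
  as.integer(min(4, max(2, k)))
}

#' Select spline df by leave-one-out cross-validation
#'
#' For each candidate df, each training observation is held out in turn, the
#' spline is refitted on the rest, and the squared prediction error at the
#' held-out day accumulated; the df with the smallest LOO error wins, ties
#' going to the smaller df.
#'
#' @param series_train training observations (>= 5).
#' @param grid candidate dfs; default `2:min(10, n - 2)`.
#' @return list `df` (selected), `loo` (named error per candidate).
#' @export
select_df_loocv <- function(series_train, grid = NULL) {
  n <- nrow(series_train)
  if (n < 5) stop("select_df_loocv: need >= 5 training observations")
  if (is.null(grid)) grid <- seq(2L, max(2L, min(10L, n - 2L)))
  errs <- stats::setNames(rep(NA_real_, length(grid)), grid)
  for (g in seq_along(grid)) {
    df <- grid[g]
    se <- 0; ok <- TRUE
    for (i in seq_len(n)) {
      tr <- series_train[-i, , drop = FALSE]
      if (nrow(tr) <= df || nrow(tr) < 4) { ok <- FALSE; break }
      fit <- stats::smooth.spline(tr$day, tr$score, df = df, cv = FALSE,
                                  all.knots = TRUE,
                                  control.spar = list(tol = 1e-10,
                                                      eps = 1e-11))
      pred <- stats::predict(fit, series_train$day[i])$y
      se <- se + (series_train$score[i] - pred)^2
    }
    if (ok) errs[g] <- se / n
  }
  if (all(is.na(errs))) stop("select_df_loocv: no feasible df in grid")
  best <- grid[which.min(errs)]   # which.min takes the first (smallest df)
  list(df = best, loo = errs)
}

#' Latent series for one subject under one method and scope
#'
#' @param series assessment data frame (`day`, `score`).
#' @param method one of `"locf"`, `"cs4"`, `"cs24"`, `"cscv"`, `"none"`
#'   (no interpolation: values only at assessment days).
#' @param scope `"full_series"` or `"train_only"`.
#' @param split_day last training day; also defines the training
#'   observations used by `cs24` / `cscv` df selection under either scope.
#' @return data frame `day`, `value`, `method`, `df_used`, `scope`.
#' @export
latent_series <- function(series, method = c("locf", "cs4", "cs24", "cscv",
                                             "none"),
                          scope = c("full_series", "train_only"),
                          split_day = NULL) {
  method <- match.arg(method)
  scope <- match.arg(scope)
  if (method == "none") {
    s <- in_scope(series, scope, split_day)
    return(data.frame(day = s$day, value = s$score, method = "none",
                      df_used = NA_real_, scope = scope))
  }
  if (method == "locf") return(interpolate_locf(series, scope, split_day))
  train <- if (is.null(split_day)) series else
    series[series$day <= split_day, , drop = FALSE]
  df <- switch(method,
    cs4 = 4,
    cs24 = df_from_categories(train),
    cscv = select_df_loocv(train)$df)
  out <- tryCatch(
    fit_smoothing_spline(series, df, scope, split_day),
    error = function(e) interpolate_locf(series, scope, split_day))
  out$method <- method
  out
}
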