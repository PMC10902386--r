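#' Prediction accuracy, significance, and variance partition
#'
#' Group-level and per-subject accuracy (MAPE, Pearson R, R-squared), a
#' one-sided correlation test and a likelihood-ratio test for R-squared,
#' Benjamini-Hochberg FDR control across subjects, prediction-horizon
#' curves, log2 fold changes against the study-day baseline, top-predictor
#' reports from idiographic coefficients, and a linear-mixed-model variance
#' partition of the assessment scores.
#'
#' @name evaluation
NULL

MAPE_EPS <- 1   # denominator guard: CAT-DI can legitimately be 0

#' Mean absolute percentage error
#'
#' `100 * mean(|o - p| / max(o, 1))`; pairs with a missing prediction are
#' dropped first.
#'
#' @param observed,predicted paired numeric vectors.
#' @return MAPE in percent, or `NA` when no valid pairs remain.
#' @export
mape <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  if (!any(ok)) return(NA_real_)
  100 * mean(abs(observed[ok] - predicted[ok]) /
             pmax(observed[ok], MAPE_EPS))
}

#' Correlation and regression accuracy tests
#'
#' Pearson R with a one-sided (rho > 0) test, R-squared (in percent) from
#' regressing observed on predicted, and a likelihood-ratio test of that
#' regression against an intercept-only model.
#'
#' @param observed,predicted paired numeric vectors (>= 3 valid pairs).
#' @return list `r`, `r2` (percent), `p_r`, `p_lrt`, `n`; `NA`s with a
#'   `degenerate = TRUE` flag when either vector has zero variance.
#' @export
accuracy_tests <- function(observed, predicted) {
  ok <- !is.na(observed) & !is.na(predicted)
  o <- observed[ok]; p <- predicted[ok]
  n <- length(o)
  if (n < 3) return(list(r = NA_real_, r2 = NA_real_, p_r = NA_real_,
                         p_lrt = NA_real_, n = n, degenerate = TRUE))
  if (stats::sd(o) == 0 || stats::sd(p) == 0)
    return(list(r = NA_real_, r2 = NA_real_, p_r = NA_real_,
                p_lrt = NA_real_, n = n, degenerate = TRUE))
  ct <- stats::cor.test(o, p, alternative = "greater", method = "pearson")
  m1 <- stats::lm(o ~ p)
  m0 <- stats::lm(o ~ 1)
  lrt <- 2 * (stats::logLik(m1) - stats::logLik(m0))
  p_lrt <- stats::pchisq(as.numeric(lrt), df = 1, lower.tail = FALSE)
  # R^2 of observed ~ predicted: identical to the squared Pearson r in a
  # single-predictor regression
  list(r = unname(ct$estimate), r2 = 100 * unname(ct$estimate)^2,
       p_r = ct$p.value, p_lrt = p_lrt, n = n, degenerate = FALSE)
}

#' Benjamini-Hochberg FDR across subjects
#'
#' @param p numeric p-values in `[0,1]` (NAs allowed, never rejected).
#' @param q FDR level.
#' @param r optional correlation estimates; when given, significance
#'   additionally requires `r > 0`.
#' @return list `q_values`, `significant` (logical).
#' @export
bh_fdr <- function(p, q = 0.05, r = NULL) {
  qv <- stats::p.adjust(p, method = "BH")
  sig <- !is.na(qv) & qv < q
  if (!is.null(r)) sig <- sig & !is.na(r) & r > 0
  list(q_values = qv, significant = sig)
}

#' R-squared by prediction horizon
#'
#' Pools observed/predicted pairs, bins them by weeks ahead of the last
#' training observation, and reports R-squared with a seeded bootstrap CI
#' per bin; bins with fewer than `min_pairs` pairs are suppressed.
#'
#' @param predictions data frame with `value`, `weeks_ahead`.
#' @param observed numeric vector aligned with `predictions`.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @param min_pairs minimum pairs per bin.
#' @return data frame `weeks_ahead`, `r2`, `lo`, `hi`, `n`.
#' @export
horizon_curve <- function(predictions, observed, n_boot = 1000L, seed = 1L,
                          min_pairs = 10L) {
  stopifnot(nrow(predictions) == length(observed))
  ok <- !is.na(predictions$value) & !is.na(observed) &
    !is.na(predictions$weeks_ahead)
  df <- data.frame(o = observed[ok], p = predictions$value[ok],
                   w = predictions$weeks_ahead[ok])
  set.seed(seed)
  rows <- lapply(sort(unique(df$w)), function(w) {
    sub <- df[df$w == w, ]
    if (nrow(sub) < min_pairs) return(NULL)
    r2 <- accuracy_tests(sub$o, sub$p)$r2
    bs <- replicate(n_boot, {
      i <- sample.int(nrow(sub), replace = TRUE)
      if (stats::sd(sub$o[i]) == 0 || stats::sd(sub$p[i]) == 0) NA_real_
      else 100 * stats::cor(sub$o[i], sub$p[i])^2
    })
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE)
    data.frame(weeks_ahead = w, r2 = r2, lo = ci[1], hi = ci[2],
               n = nrow(sub))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(weeks_ahead = numeric(0),
                                      r2 = numeric(0), lo = numeric(0),
                                      hi = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Log2 fold change of accuracy vs. the baseline model
#'
#' Negative MAPE fold change (and positive R-squared fold change) means the
#' feature-based model beats the baseline.
#'
#' @param metrics_feature,metrics_baseline lists or vectors carrying `mape`
#'   and optionally `r2` for the same evaluation pairs.
#' @return named vector `log2_mape` (and `log2_r2` when both provide r2).
#' @export
fold_change_vs_baseline <- function(metrics_feature, metrics_baseline) {
  mf <- metrics_feature[["mape"]]; mb <- metrics_baseline[["mape"]]
  out <- c(log2_mape = if (!is.null(mb) && !is.na(mb) && mb > 0)
    log2(mf / mb) else NA_real_)
  rf <- metrics_feature[["r2"]]; rb <- metrics_baseline[["r2"]]
  if (!is.null(rf) && !is.null(rb))
    out <- c(out, log2_r2 = if (!is.na(rb) && rb > 0)
      log2(rf / rb) else NA_real_)
  out
}

#' Top predictors from idiographic models
#'
#' Features whose elastic-net odds ratio falls outside `[1 - threshold,
#' 1 + threshold]`, per subject, ranked by `|log OR|`, with a cohort summary
#' of how often each feature passes.
#'
#' @param models named list of fitted logistic `mood_enet` objects (one per
#'   subject).
#' @param threshold OR band half-width (default 0.05, i.e. OR outside
#'   `[0.95, 1.05]`).
#' @return list `per_subject` (data frame subject/feature/or/rank) and
#'   `summary` (feature counts across subjects).
#' @export
top_predictors <- function(models, threshold = 0.05) {
  rows <- lapply(names(models), function(s) {
    m <- models[[s]]
    cf <- m$coef[names(m$coef) != "(Intercept)"]
    or <- exp(cf)
    pass <- which(or > 1 + threshold | or < 1 - threshold)
    if (!length(pass)) return(NULL)
    d <- data.frame(subject = s, feature = names(or)[pass],
                    or = unname(or[pass]),
                    abs_log_or = abs(log(unname(or[pass]))))
    d <- d[order(-d$abs_log_or), ]
    d$rank <- seq_len(nrow(d))
    d
  })
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject))
    per_subject <- data.frame(subject = character(0), feature = character(0),
                              or = numeric(0), abs_log_or = numeric(0),
                              rank = integer(0))
  summary <- if (nrow(per_subject))
    as.data.frame(sort(table(per_subject$feature), decreasing = TRUE),
                  stringsAsFactors = FALSE)
  else data.frame(Var1 = character(0), Freq = integer(0))
  names(summary) <- c("feature", "n_subjects")
  list(per_subject = per_subject, summary = summary)
}

#' Planted-effect recovery against a top-predictor report
#'
#' For each subject of a single-loading recovery cohort, checks whether the
#' planted feature — or any extracted feature its driver mechanically moves
#' (see [driven_features()]), or a trailing-mean transform of one — appears
#' in the subject's top-predictor report with the sign the ground truth
#' implies.
#'
#' @param report a [top_predictors()] result from idiographic logistic
#'   models.
#' @param planted data frame subject / feature / sign (from
#'   [simulate_recovery_cohort()]).
#' @param fitted_subjects subjects that actually have a fitted model.
#' @return list `rate`, `n`, and the per-subject logical `hit`.
#' @export
planted_recovery <- function(report, planted,
                             fitted_subjects = unique(planted$subject)) {
  keep <- planted$subject %in% fitted_subjects
  planted <- planted[keep, , drop = FALSE]
  hit <- logical(nrow(planted))
  for (i in seq_len(nrow(planted))) {
    rep_i <- report$per_subject[
      report$per_subject$subject == planted$subject[i], , drop = FALSE]
    dr <- driven_features(planted$feature[i])
    for (k in seq_along(dr)) {
      fam <- rep_i[grepl(paste0("^", names(dr)[k], "($|_mean\\d)"),
                         rep_i$feature), , drop = FALSE]
      if (nrow(fam) &&
          any(sign(log(fam$or)) == planted$sign[i] * dr[k])) {
        hit[i] <- TRUE
        break
      }
    }
  }
  list(rate = mean(hit), n = nrow(planted),
       hit = stats::setNames(hit, planted$subject))
}

#' Variance partition of assessment scores
#'
#' Fits a linear mixed model by maximum likelihood with the given random
#' intercepts and fixed covariates, computes each fixed effect's variance by
#' the post-hoc `var(X beta)` calculation, and reports every component as a
#' fraction of the total (random variances + fixed post-hoc variances +
#' residual). Confidence intervals come from a nonparametric bootstrap over
#' subjects.
#'
#' @param data long data frame with a `score` column.
#' @param random columns modeled as random intercepts (must include the
#'   subject id column first).
#' @param fixed columns modeled as fixed effects.
#' @param n_boot bootstrap resamples over subjects (0 skips CIs).
#' @param seed bootstrap seed.
#' @return data frame `component`, `fraction`, `lo`, `hi`; fractions sum to
#'   1 with the residual row.
#' @export
variance_partition <- function(data, random = "subject", fixed = character(0),
                               n_boot = 0L, seed = 1L) {
  stopifnot("score" %in% names(data), length(random) >= 1)
  fractions <- function(d) {
    rterms <- paste0("(1|", random, ")")
    fterms <- if (length(fixed)) fixed else NULL
    form <- stats::reformulate(c(fterms, rterms), response = "score")
    fit <- lme4::lmer(form, data = d, REML = FALSE,
                      control = lme4::lmerControl(calc.derivs = FALSE))
    vc <- lme4::VarCorr(fit)
    rand_var <- vapply(random, function(g) as.numeric(vc[[g]]), 0)
    resid_var <- attr(vc, "sc")^2
    fix_var <- if (length(fixed)) {
      mm <- stats::model.matrix(fit)
      beta <- lme4::fixef(fit)
      vapply(fixed, function(f) {
        cols <- grep(paste0("^", f), colnames(mm), value = TRUE)
        cols <- setdiff(cols, "(Intercept)")
        if (!length(cols)) return(0)
        stats::var(as.numeric(mm[, cols, drop = FALSE] %*%
                              beta[cols]))
      }, 0)
    } else numeric(0)
    tot <- sum(rand_var) + sum(fix_var) + resid_var
    c(rand_var, fix_var, residual = resid_var) / tot
  }
  fr <- fractions(data)
  out <- data.frame(component = names(fr), fraction = unname(fr),
                    lo = NA_real_, hi = NA_real_)
  if (n_boot > 0) {
    set.seed(seed)
    subj_col <- random[1]
    ids <- unique(data[[subj_col]])
    bs <- replicate(n_boot, {
      take <- sample(ids, replace = TRUE)
      d <- do.call(rbind, lapply(seq_along(take), function(k) {
        dd <- data[data[[subj_col]] == take[k], , drop = FALSE]
        dd[[subj_col]] <- paste0("bs", k)
        dd
      }))
      tryCatch(fractions(d), error = function(e) rep(NA_real_, length(fr)))
    })
    bs <- matrix(bs, nrow = length(fr))
    out$lo <- apply(bs, 1, stats::quantile, 0.025, na.rm = TRUE)
    out$hi <- apply(bs, 1, stats::quantile, 0.975, na.rm = TRUE)
  }
  out
}
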