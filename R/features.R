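#' Feature expansion, imputation, and standardization
#'
#' Daily features are expanded with trailing-window means and variances
#' (windows of 3, 7, 14, 30 strictly prior days) and with contrasts between
#' windows of different lengths (e.g. last night's sleep vs. the past week's
#' mean). Per subject, features with > 90% training-split missingness are
#' dropped, the remainder imputed by iterative soft-thresholded SVD matrix
#' completion fitted on the training split alone, then z-scored with
#' training-set statistics. Nothing downstream of the split ever touches a
#' fit.
#'
#' @name feature_pipeline
NULL

ROLL_WINDOWS <- c(3L, 7L, 14L, 30L)

#' Trailing-window means and variances
#'
#' For each base feature and window length `w`, the mean and variance over
#' days `[t - w, t - 1]` (strictly prior days). Windows observing fewer than
#' `ceiling(w / 2)` days are set to missing.
#'
#' @param mat numeric matrix, rows = consecutive calendar days, columns =
#'   base features, NA for missing.
#' @param windows integer window lengths.
#' @return matrix of `ncol(mat) * length(windows) * 2` columns named
#'   `<feature>_mean<w>` / `<feature>_var<w>`.
#' @export
rolling_stats <- function(mat, windows = ROLL_WINDOWS) {
  n <- nrow(mat)
  res <- list()
  for (w in windows) {
    need <- ceiling(w / 2)
    for (j in seq_len(ncol(mat))) {
      x <- mat[, j]
      obs <- !is.na(x)
      x0 <- ifelse(obs, x, 0)
      cs <- cumsum(x0); cs2 <- cumsum(x0^2); cn <- cumsum(obs)
      # window ending at day t-1, i.e. over rows (t-w)..(t-1)
      idx_hi <- seq_len(n) - 1L
      idx_lo <- pmax(idx_hi - w, 0L)
      at <- function(v, i) ifelse(i >= 1, v[pmax(i, 1)], 0)
      s <- at(cs, idx_hi) - at(cs, idx_lo)
      s2 <- at(cs2, idx_hi) - at(cs2, idx_lo)
      k <- at(cn, idx_hi) - at(cn, idx_lo)
      m <- ifelse(k >= need, s / k, NA_real_)
      v <- ifelse(k >= pmax(need, 2),
                  pmax(0, (s2 - s^2 / k) / (k - 1)), NA_real_)
      res[[paste0(colnames(mat)[j], "_mean", w)]] <- m
      res[[paste0(colnames(mat)[j], "_var", w)]] <- v
    }
  }
  do.call(cbind, res)
}

#' Window contrasts between short- and long-window means
#'
#' For each ordered pair `w1 < w2` from {1, 3, 7, 14, 30} (window 1 being
#' the same-day raw value), the difference `mean_w1 - mean_w2` and the ratio
#' `mean_w1 / (mean_w2 + 1e-6)`. Missing whenever either side is missing.
#'
#' @param raw base daily matrix (window 1).
#' @param rolled a [rolling_stats()] result aligned with `raw`.
#' @param ratios include the ratio variant (default TRUE).
#' @return matrix of contrast features.
#' @export
window_contrasts <- function(raw, rolled, ratios = TRUE) {
  eps <- 1e-6
  ws <- c(1L, ROLL_WINDOWS)
  res <- list()
  get_mean <- function(f, w) {
    if (w == 1L) raw[, f] else rolled[, paste0(f, "_mean", w)]
  }
  for (f in colnames(raw)) {
    for (i in seq_along(ws)) for (j in seq_along(ws)) {
      if (i >= j) next
      a <- get_mean(f, ws[i]); b <- get_mean(f, ws[j])
      res[[paste0(f, "_d", ws[i], "v", ws[j])]] <- a - b
      if (ratios) res[[paste0(f, "_r", ws[i], "v", ws[j])]] <- a / (b + eps)
    }
  }
  do.call(cbind, res)
}

#' Drop features too sparse in the training split
#'
#' @param mat day x feature matrix for one subject.
#' @param train_rows logical or integer index of training days.
#' @param max_missing strict threshold: features with training missingness
#'   fraction > `max_missing` are removed.
#' @return list `mat` (reduced), `dropped` (names removed).
#' @export
drop_sparse_features <- function(mat, train_rows, max_missing = 0.90) {
  frac <- colMeans(is.na(mat[train_rows, , drop = FALSE]))
  dropped <- colnames(mat)[frac > max_missing]
  if (length(dropped) == ncol(mat))
    stop("drop_sparse_features: all features exceed missingness threshold")
  list(mat = mat[, frac <= max_missing, drop = FALSE], dropped = dropped)
}

#' Fit a soft-thresholded SVD matrix-completion model
#'
#' Iterates: fill missing entries with the current low-rank estimate, take
#' the SVD, soft-threshold the singular values by `lambda`, reconstruct.
#' The objective 0.5 * ||P_obs(X - Z)||_F^2 + lambda * ||Z||_* is
#' non-increasing across iterations. Columns are centered on their observed
#' training means first.
#'
#' @param train day x feature matrix with NAs (training split only).
#' @param lambda soft threshold; default 1/5 of the top singular value of
#'   the mean-filled training matrix.
#' @param max_rank cap on retained rank (default `min(50, dim - 1)`).
#' @param tol relative Frobenius-change convergence tolerance.
#' @param max_iter iteration cap; non-convergence sets `converged = FALSE`.
#' @return object of class `soft_impute` with factors `u`, `d`, `v`, column
#'   means, `lambda`, the objective trace, and the retained feature names.
#' @export
soft_impute_fit <- function(train, lambda = NULL, max_rank = NULL,
                            tol = 1e-5, max_iter = 500) {
  stopifnot(is.matrix(train))
  obs <- !is.na(train)
  if (any(colSums(obs) < 2))
    stop("soft_impute_fit: every feature needs >= 2 observed training entries")
  mu <- colMeans(train, na.rm = TRUE)
  # internal column scaling so heterogeneous units share one threshold;
  # undone on reconstruction, so observed entries are still preserved
  sc <- apply(train, 2, stats::sd, na.rm = TRUE)
  sc[!is.finite(sc) | sc <= 0] <- 1
  xc <- sweep(sweep(train, 2, mu), 2, sc, "/")
  xc[!obs] <- 0
  if (is.null(max_rank)) max_rank <- min(50L, dim(train) - 1L)
  if (is.null(lambda)) lambda <- svd(xc, nu = 0, nv = 0)$d[1] / 5
  z <- matrix(0, nrow(train), ncol(train))
  objective <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    x_fill <- xc
    x_fill[!obs] <- z[!obs]
    sv <- svd(x_fill)
    d_new <- pmax(sv$d - lambda, 0)
    r <- min(max_rank, sum(d_new > 0))
    z_new <- if (r == 0) matrix(0, nrow(train), ncol(train)) else
      sv$u[, seq_len(r), drop = FALSE] %*%
      (d_new[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
    objective <- c(objective,
                   0.5 * sum((xc[obs] - z_new[obs])^2) + lambda * sum(d_new))
    delta <- sqrt(sum((z_new - z)^2)) / max(sqrt(sum(z^2)), 1e-12)
    z <- z_new
    r_keep <- max(r, 1L)
    u <- sv$u[, seq_len(r_keep), drop = FALSE]
    d <- d_new[seq_len(r_keep)]
    v <- sv$v[, seq_len(r_keep), drop = FALSE]
    if (it > 1 && delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("soft_impute_fit: not converged after ", max_iter, " iterations")
  structure(list(u = u, d = d, v = v, mu = mu, sc = sc, lambda = lambda,
                 features = colnames(train), objective = objective,
                 converged = converged),
            class = "soft_impute")
}

#' Apply a fitted soft-impute model to complete a matrix
#'
#' Observed entries are left untouched. For each row, a ridge projection of
#' the observed (centered) entries onto the fitted right factors gives the
#' row's latent coordinates, from which missing cells are reconstructed;
#' this works for both training rows and unseen (test) rows.
#'
#' @param model a [soft_impute_fit()].
#' @param mat matrix with the same columns as the training matrix.
#' @return completed matrix.
#' @export
soft_impute_apply <- function(model, mat) {
  stopifnot(identical(colnames(mat), model$features))
  out <- mat
  v <- model$v
  d <- model$d
  if (all(d == 0)) {
    for (j in seq_len(ncol(mat)))
      out[is.na(mat[, j]), j] <- model$mu[j]
    return(out)
  }
  lam <- model$lambda
  for (i in which(rowSums(is.na(mat)) > 0)) {
    o <- !is.na(mat[i, ])
    if (!any(o)) {
      out[i, !o] <- model$mu[!o]
      next
    }
    vo <- v[o, , drop = FALSE]
    xo <- (mat[i, o] - model$mu[o]) / model$sc[o]
    a <- solve(crossprod(vo) + diag(lam / (d + 1e-12), ncol(v)),
               crossprod(vo, xo))
    fill <- as.numeric(v[!o, , drop = FALSE] %*% a)
    out[i, !o] <- model$mu[!o] + fill * model$sc[!o]
  }
  out
}

#' Training-set standardization
#'
#' @param mat day x feature matrix.
#' @param train_rows index of training days.
#' @return list `stats` (means, sds, kept feature names) after dropping
#'   zero-variance training features, and `mat`, the z-scored matrix
#'   (training statistics applied to all rows).
#' @export
standardize_features <- function(mat, train_rows) {
  mu <- colMeans(mat[train_rows, , drop = FALSE], na.rm = TRUE)
  sd_ <- apply(mat[train_rows, , drop = FALSE], 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sd_) & sd_ > 0
  z <- sweep(sweep(mat[, keep, drop = FALSE], 2, mu[keep]), 2, sd_[keep], "/")
  list(mat = z,
       stats = list(mean = mu[keep], sd = sd_[keep],
                    kept = colnames(mat)[keep],
                    dropped = colnames(mat)[!keep]))
}

#' Per-subject feature pipeline: expand, drop, impute, standardize
#'
#' All fitting (sparsity decisions, imputation, scaling) uses training rows
#' only; the fitted transforms are then applied to every day.
#'
#' @param daily day x feature matrix of raw daily features for one subject
#'   (row `d` = study day `d`).
#' @param train_days integer study days in the training split.
#' @param expand add rolling statistics and window contrasts (default TRUE);
#'   FALSE keeps raw features only (a reduced pipeline for large null
#'   cohorts).
#' @param ratios include ratio contrasts.
#' @param lambda,max_rank,tol,max_iter soft-impute controls.
#' @return list with `x` (completed, standardized day x feature matrix),
#'   `model` (the `soft_impute` fit), `scale` (training statistics),
#'   `dropped_sparse`, and `feature_names`.
#' @export
prepare_features <- function(daily, train_days, expand = TRUE, ratios = TRUE,
                             lambda = NULL, max_rank = NULL, tol = 1e-5,
                             max_iter = 500) {
  stopifnot(is.matrix(daily))
  full <- if (expand) {
    rolled <- rolling_stats(daily)
    cbind(daily, rolled, window_contrasts(daily, rolled, ratios))
  } else daily
  train_rows <- intersect(train_days, seq_len(nrow(full)))
  ds <- drop_sparse_features(full, train_rows)
  # drop columns exactly duplicating an earlier one on the training rows
  # (e.g. the longest-off-period endpoints duplicate bed/wake times):
  # identical columns split elastic-net weight arbitrarily
  tr <- ds$mat[train_rows, , drop = FALSE]
  dup <- duplicated(lapply(seq_len(ncol(tr)), function(j) tr[, j]))
  ds$mat <- ds$mat[, !dup, drop = FALSE]
  model <- soft_impute_fit(ds$mat[train_rows, , drop = FALSE],
                           lambda = lambda, max_rank = max_rank, tol = tol,
                           max_iter = max_iter)
  xi <- soft_impute_apply(model, ds$mat)
  sf <- standardize_features(xi, train_rows)
  list(x = sf$mat, model = model, scale = sf$stats,
       dropped_sparse = ds$dropped, feature_names = colnames(sf$mat))
}
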