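#' Fit a PLS1 regression model (NIPALS)
#'
#' Single-response partial least squares with column mean-centering and no
#' variance scaling (the standard choice for derivative spectra, which share
#' units). Each component takes the weight vector `w = X'y / |X'y|`, score
#' `t = X w`, loadings `p = X't / t't`, `q = y't / t't`, then deflates `X`
#' and `y`. Regression vectors for every component count `1..ncomp` are
#' assembled as `B_a = W_a (P_a' W_a)^{-1} q_a`, so a single fit yields the
#' whole coefficient path.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric response (analyte concentration), one value per row of
#'   `X`, not constant.
#' @param ncomp number of latent components, at most `min(nrow(X) - 1,
#'   ncol(X))`.
#' @param scale logical; if `TRUE`, columns of `X` are additionally scaled
#'   to unit variance (off by default).
#' @return object of class `pls1`: list with `x_mean`, `y_mean`, `x_scale`,
#'   `weights`, `x_loadings`, `y_loadings`, `scores`, `coef_path`
#'   (features x ncomp), `coefficients` (= last column), `fitted`, `ncomp`.
#' @export
pls1_fit <- function(X, y, ncomp, scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 2L) stop("need at least 2 samples")
  if (length(y) != n) stop("length(y) != nrow(X)")
  if (sd(y) == 0) stop("constant response: nothing to calibrate")
  ncomp <- as.integer(ncomp)
  if (ncomp < 1L || ncomp > min(n - 1L, p))
    stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1L, p))
  x_mean <- colMeans(X)
  x_scale <- if (scale) apply(X, 2, sd) else rep(1, p)
  if (any(x_scale == 0)) x_scale[x_scale == 0] <- 1
  y_mean <- mean(y)
  Xc <- sweep(sweep(X, 2, x_mean), 2, x_scale, "/")
  yc <- y - y_mean
  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  x0 <- sqrt(sum(crossprod(Xc, yc)^2))
  Xd <- Xc; yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw <= 1e-12 * max(x0, 1e-300))
      stop("degenerate deflation: zero weight norm at component ", a)
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t)[, 1] / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pvec)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pvec; Tm[, a] <- t; q[a] <- qa
  }
  coef_path <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    Wa <- W[, 1:a, drop = FALSE]; Pa <- P[, 1:a, drop = FALSE]
    coef_path[, a] <- Wa %*% solve(crossprod(Pa, Wa), q[1:a])
  }
  coef_path <- coef_path / x_scale
  b <- coef_path[, ncomp]
  fitted <- as.numeric(y_mean + sweep(X, 2, x_mean) %*% b)
  structure(
    list(x_mean = x_mean, y_mean = y_mean, x_scale = x_scale, weights = W,
         x_loadings = P, y_loadings = q, scores = Tm, coef_path = coef_path,
         coefficients = b, fitted = fitted, ncomp = ncomp),
    class = "pls1")
}

#' Predict from a PLS1 model
#' @param object a [pls1_fit()] model.
#' @param newdata numeric matrix with the training feature count.
#' @param ncomp component count to predict with (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predicted concentrations.
#' @export
predict.pls1 <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean))
    stop("newdata has ", ncol(newdata), " features; model was trained on ",
         length(object$x_mean))
  if (ncomp < 1L || ncomp > object$ncomp)
    stop("ncomp must be in 1..", object$ncomp)
  b <- object$coef_path[, ncomp]
  as.numeric(object$y_mean + sweep(newdata, 2, object$x_mean) %*% b)
}

#' @export
print.pls1 <- function(x, ...) {
  cat("<pls1> ", x$ncomp, " component(s), ", length(x$x_mean),
      " features\n", sep = "")
  invisible(x)
}

#' Calibration metrics
#'
#' `r2 = 1 - SSE/SST`, root-mean-square error and mean absolute error of
#' predictions against reference values. With a constant reference, `r2` is
#' undefined and returned as `NA` (rmse/mae are still computed).
#'
#' @param y_true,y_pred numeric vectors of equal length (at least 2).
#' @return list with `r2`, `rmse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 values")
  err <- y_true - y_pred
  sst <- sum((y_true - mean(y_true))^2)
  list(r2 = if (sst == 0) NA_real_ else 1 - sum(err^2) / sst,
       rmse = sqrt(mean(err^2)),
       mae = mean(abs(err)))
}

#' Leave-one-out cross-validated PLS1 calibration
#'
#' Holds out one group at a time (one spectrum per fold with
#' `grouping = "per_spectrum"`; all replicate acquisitions of one physical
#' sample together with `grouping = "per_sample"`, which guards against
#' replicate leakage), fits on the remainder, and pools predictions. The
#' mean absolute error is computed for every candidate component count
#' `1..max_components`; the chosen count minimizes MAE (ties break toward
#' fewer components). The final model is refit on the full data with that
#' count, and the validation determination coefficient `r2_validation =
#' 1 - SSE/SST` of the pooled cross-validated predictions is reported.
#'
#' @param X numeric matrix, samples x features.
#' @param y numeric concentrations.
#' @param max_components most components to consider; default
#'   `min(10, groups - 2, ncol(X))`, further capped so every fold can fit.
#' @param grouping `"per_spectrum"` or `"per_sample"`; ignored when
#'   `groups` is given.
#' @param groups optional explicit fold labels (one per row of `X`).
#' @param sample_ids physical-sample labels used by `"per_sample"`
#'   (typically `level_id`); required for that grouping.
#' @return object of class `calibration_result`: list with `model`,
#'   `loo_predictions`, `n_factors_chosen`, `mae_by_factors`,
#'   `r2_validation`, `rmse`, `mae`, `groups`, `y`,
#'   `loo_prediction_path` (samples x candidate counts).
#' @export
loo_cv <- function(X, y, max_components = NULL,
                   grouping = c("per_spectrum", "per_sample"),
                   groups = NULL, sample_ids = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  grouping <- match.arg(grouping)
  if (is.null(groups)) {
    groups <- if (grouping == "per_spectrum") seq_len(nrow(X)) else {
      if (is.null(sample_ids))
        stop("per_sample grouping needs sample_ids (e.g. level ids)")
      sample_ids
    }
  }
  groups <- as.character(groups)
  if (length(groups) != nrow(X)) stop("one group label per row required")
  gl <- unique(groups)
  if (length(gl) < 3L) stop("need at least 3 cross-validation groups, got ",
                            length(gl))
  min_train <- nrow(X) - max(table(groups))
  cap <- min(min_train - 1L, ncol(X))
  if (is.null(max_components))
    max_components <- min(10L, length(gl) - 2L, ncol(X))
  max_components <- min(as.integer(max_components), cap)
  if (max_components < 1L) stop("no admissible component count")
  preds <- matrix(NA_real_, nrow(X), max_components)
  achieved <- max_components
  for (g in gl) {
    hold <- groups == g
    fit <- .pls1_fit_shrink(X[!hold, , drop = FALSE], y[!hold],
                            max_components)
    achieved <- min(achieved, fit$ncomp)
    for (a in seq_len(fit$ncomp))
      preds[hold, a] <- predict(fit, X[hold, , drop = FALSE], ncomp = a)
  }
  # noise-free or collinear folds can exhaust the data's rank before
  # max_components; candidate counts are truncated to what every fold fit
  max_components <- achieved
  preds <- preds[, seq_len(achieved), drop = FALSE]
  mae_by_factors <- colMeans(abs(preds - y))
  n_chosen <- which.min(mae_by_factors)   # first minimum = fewest factors
  loo_pred <- preds[, n_chosen]
  met <- regression_metrics(y, loo_pred)
  structure(
    list(model = .pls1_fit_shrink(X, y, n_chosen),
         loo_predictions = loo_pred,
         n_factors_chosen = n_chosen,
         mae_by_factors = as.numeric(mae_by_factors),
         r2_validation = met$r2, rmse = met$rmse, mae = met$mae,
         groups = groups, y = y, loo_prediction_path = preds),
    class = "calibration_result")
}

# largest fit with at most ncomp components; backs off when the data's
# rank is exhausted (degenerate deflation)
.pls1_fit_shrink <- function(X, y, ncomp) {
  while (ncomp >= 1L) {
    fit <- tryCatch(pls1_fit(X, y, ncomp), error = function(e) {
      if (grepl("degenerate deflation", conditionMessage(e))) NULL
      else stop(e)
    })
    if (!is.null(fit)) return(fit)
    ncomp <- ncomp - 1L
  }
  stop("no admissible component count: response orthogonal to predictors")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result> ", length(x$y), " samples, ",
      x$n_factors_chosen, " factor(s)\n", sep = "")
  cat(sprintf("  LOO R2 = %.4f, RMSE = %.4g, MAE = %.4g\n",
              x$r2_validation, x$rmse, x$mae))
  invisible(x)
}

#' Export a calibration result (per-sample CSV + JSON summary)
#' @param cr a [loo_cv()] result.
#' @param csv_path per-sample CSV (`sample_id, y_true, y_loo_pred`).
#' @param json_path JSON summary path.
#' @param sample_ids optional ids for the CSV rows.
#' @return invisibly, `csv_path`.
#' @export
write_calibration <- function(cr, csv_path, json_path,
                              sample_ids = seq_along(cr$y)) {
  fmt <- function(x) sprintf("%.17g", x)
  write.csv(data.frame(sample_id = sample_ids, y_true = fmt(cr$y),
                       y_loo_pred = fmt(cr$loo_predictions)),
            csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(n_factors_chosen = cr$n_factors_chosen,
         r2_validation = cr$r2_validation, rmse = cr$rmse, mae = cr$mae,
         mae_by_factors = cr$mae_by_factors),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
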