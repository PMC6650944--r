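#' Regression metrics: R-squared, RMSE, NRMSE
#'
#' `RMSE = sqrt(mean((observed - predicted)^2))`; `NRMSE = RMSE / mean(observed)`
#' (reported as a fraction; multiply by 100 for percent); `R2` is the
#' standard coefficient of determination `1 - SSres/SStot` on
#' measured-versus-predicted pairs.
#'
#' @param observed Measured response values (length >= 2, nonzero mean).
#' @param predicted Predictions of the same length.
#' @return Named numeric: `r2`, `rmse`, `nrmse`.
#' @export
regression_metrics <- function(observed, predicted) {
  if (length(observed) < 2 || length(observed) != length(predicted))
    stop("need >= 2 observed/predicted pairs of equal length")
  ok <- is.finite(observed) & is.finite(predicted)
  observed <- observed[ok]; predicted <- predicted[ok]
  m <- mean(observed)
  if (m == 0) stop("mean(observed) is zero; NRMSE undefined")
  ss_tot <- sum((observed - m)^2)
  if (ss_tot == 0) stop("constant observed values; R2 undefined")
  rmse <- sqrt(mean((observed - predicted)^2))
  c(r2 = 1 - sum((observed - predicted)^2) / ss_tot,
    rmse = rmse,
    nrmse = rmse / m)
}

#' Descriptive statistics of an LNC vector
#'
#' @param y Numeric vector (length >= 2).
#' @return Named numeric: `n`, `max`, `min`, `mean`, `sd` (n-1 denominator),
#'   `cv` (= sd/mean).
#' @export
descriptive_stats <- function(y) {
  if (length(y) < 2) stop("need at least 2 values")
  m <- mean(y)
  s <- stats::sd(y)
  cv <- if (s == 0) 0 else { if (m == 0) stop("mean is zero; CV undefined"); s / m }
  c(n = length(y), max = max(y), min = min(y), mean = m, sd = s, cv = cv)
}

# Linear coefficients (intercept + slopes) of any model whose prediction is
# linear in X, recovered by probing the prediction map.
linear_coefficients <- function(predict_fun, p, names) {
  b0 <- predict_fun(matrix(0, 1, p, dimnames = list(NULL, names)))
  b <- vapply(seq_len(p), function(j) {
    e <- matrix(0, 1, p, dimnames = list(NULL, names))
    e[1, j] <- 1
    predict_fun(e) - b0
  }, numeric(1))
  stats::setNames(c(b0, b), c("(Intercept)", names))
}

#' Fit a PLS regression of LNC on spectral features
#'
#' Single-response partial least squares: latent components maximizing
#' covariance between projections of `X` and `y`, robust to the strong
#' collinearity of spectral variables. The component count is chosen by
#' leave-one-out cross-validation minimizing RMSE (capped at
#' `min(p, n - 1)`) unless given. The final model is linear in the original
#' features; coefficients in that space are reported. With a single
#' predictor the fit reduces to simple least squares (identical to
#' one-component PLS).
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param y Response vector.
#' @param ncomp Number of components, or `NULL` for LOO-CV choice.
#' @return Object of class `lnc_pls` with elements `coefficients`, `ncomp`,
#'   `cv_rmse` (per candidate component count, when CV ran) and `features`.
#' @export
fit_pls <- function(X, y, ncomp = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  y <- as.numeric(y)
  if (stats::sd(y) == 0) stop("constant response; nothing to fit")
  max_comp <- min(p, n - 1L, qr(scale(X, scale = FALSE))$rank)
  if (!is.null(ncomp) && ncomp > max_comp) {
    warning("ncomp reduced to rank limit ", max_comp)
    ncomp <- max_comp
  }
  fit_at <- function(Xtr, ytr, nc) {
    if (ncol(Xtr) == 1L) {
      cf <- stats::coef(stats::lm.fit(cbind(1, Xtr), ytr))
      function(newx) as.numeric(cbind(1, as.matrix(newx)) %*% cf)
    } else {
      m <- mixOmics::pls(Xtr, ytr, ncomp = nc, mode = "regression",
                         scale = TRUE)
      function(newx) {
        nd <- as.matrix(newx)
        colnames(nd) <- colnames(Xtr)
        pr <- stats::predict(m, nd)$predict
        as.numeric(pr[, 1, nc])
      }
    }
  }
  cv_rmse <- NULL
  if (is.null(ncomp)) {
    cand <- seq_len(max_comp)
    if (p == 1L) {
      ncomp <- 1L
    } else {
      press <- matrix(NA_real_, n, length(cand))
      for (i in seq_len(n)) {
        m <- mixOmics::pls(X[-i, , drop = FALSE], y[-i], ncomp = max_comp,
                           mode = "regression", scale = TRUE)
        pr <- stats::predict(m, X[i, , drop = FALSE])$predict[1, 1, ]
        press[i, ] <- (pr[cand] - y[i])^2
      }
      cv_rmse <- sqrt(colMeans(press))
      ncomp <- cand[which.min(cv_rmse)]
    }
  }
  pf <- fit_at(X, y, ncomp)
  coefs <- linear_coefficients(pf, p, colnames(X))
  structure(list(coefficients = coefs, ncomp = ncomp, cv_rmse = cv_rmse,
                 features = colnames(X)),
            class = "lnc_pls")
}

#' @export
predict.lnc_pls <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, object$features, drop = FALSE]
  as.numeric(cbind(1, nd) %*% object$coefficients)
}

#' Fit a random forest regression of LNC on spectral features
#'
#' Bootstrap-aggregated regression trees with random feature subsets per
#' split. Out-of-bag (OOB) RMSE is recorded as the internal error estimate.
#' Deterministic given the seed.
#'
#' @param X Numeric matrix (samples x features, named columns).
#' @param y Response vector (n >= 5).
#' @param ntree Number of trees (default 500).
#' @param mtry Variables tried per split (default `max(1, floor(p/3))`, the
#'   regression-forest convention).
#' @param seed RNG seed, recorded in the fit.
#' @return Object of class `lnc_rf` with the forest, `oob_rmse`,
#'   `importance` and `seed`.
#' @export
fit_rf <- function(X, y, ntree = 500, mtry = NULL, seed = 20120731) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  if (nrow(X) < 5) stop("need at least 5 samples")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(X) / 3))
  set.seed(seed)
  safe <- as.data.frame(X)
  names(safe) <- make.names(names(safe))
  forest <- randomForest::randomForest(safe, as.numeric(y), ntree = ntree,
                                       mtry = mtry, importance = TRUE)
  structure(list(forest = forest,
                 oob_rmse = sqrt(forest$mse[ntree]),
                 importance = randomForest::importance(forest)[, "%IncMSE"],
                 features = colnames(X),
                 seed = seed),
            class = "lnc_rf")
}

#' @export
predict.lnc_rf <- function(object, newdata, ...) {
  nd <- as.data.frame(as.matrix(newdata)[, object$features, drop = FALSE])
  names(nd) <- make.names(names(nd))
  as.numeric(stats::predict(object$forest, nd))
}

#' Evaluate a fitted model on a sample set
#'
#' @param model An `lnc_pls` or `lnc_rf` fit.
#' @param X Feature matrix of the evaluation set.
#' @param y Observed responses.
#' @return Named numeric `r2`, `rmse`, `nrmse` (see [regression_metrics()]).
#' @export
evaluate_model <- function(model, X, y) {
  regression_metrics(as.numeric(y), stats::predict(model, X))
}

#' Assemble a calibration/validation model report
#'
#' One row per (algorithm, set) with `n`, `r2`, `rmse`, `nrmse`, mirroring
#' the workflow's published report layout. The NRMSE = RMSE/mean identity is
#' re-checked at build time.
#'
#' @param family Feature family label (e.g. `"bands"`).
#' @param algorithm `"PLS"` or `"RF"`.
#' @param cal,val Metric vectors from [evaluate_model()].
#' @param n_cal,n_val Set sizes.
#' @param y_cal,y_val Observed responses (for the identity check).
#' @return A data.frame with two rows (calibration, validation).
#' @export
model_report <- function(family, algorithm, cal, val, n_cal, n_val,
                         y_cal, y_val) {
  stopifnot(abs(cal["nrmse"] - cal["rmse"] / mean(y_cal)) < 1e-12,
            abs(val["nrmse"] - val["rmse"] / mean(y_val)) < 1e-12)
  data.frame(family = family, algorithm = algorithm,
             set = c("calibration", "validation"),
             n = c(n_cal, n_val),
             r2 = c(cal["r2"], val["r2"]),
             rmse = c(cal["rmse"], val["rmse"]),
             nrmse = c(cal["nrmse"], val["nrmse"]),
             row.names = NULL)
}
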