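#' Standardize a design matrix
#'
#' Centers and scales columns to unit variance, dropping zero-variance
#' columns (they carry no information and break projection norms). The
#' centering/scaling record is kept for inverse transforms.
#'
#' @param X Numeric matrix with column names.
#' @return Standardized matrix with attributes `center`, `scale`,
#'   `dropped` (names of zero-variance columns).
#' @export
standardize_columns <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  keep <- sdv > 0 & is.finite(sdv)
  if (!all(keep))
    message("dropping ", sum(!keep), " zero-variance column(s): ",
            paste(utils::head(colnames(X)[!keep], 5), collapse = ", "))
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  attr(Xs, "center") <- mu[keep]
  attr(Xs, "scale") <- sdv[keep]
  attr(Xs, "dropped") <- colnames(X)[!keep]
  Xs
}

#' Successive projections chain
#'
#' Forward chain of minimally collinear variables: starting from `start`, at
#' each step every unselected column is replaced by its component orthogonal
#' to the span of the selected columns, and the column with the largest
#' residual norm is appended. Deterministic given `X` and `start`. If all
#' residual norms vanish before reaching `k` (rank deficiency) the chain is
#' truncated with a message.
#'
#' @param X Standardized design matrix (samples x variables) with column
#'   names.
#' @param start Name (or index) of the first variable.
#' @param k Chain length, `1 <= k <= min(n - 1, p)`.
#' @return Character vector of selected variable names in chain order.
#' @export
spa_chain <- function(X, start, k) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (k < 1 || k > min(n - 1, p))
    stop("k must lie in [1, min(n - 1, p)]")
  if (is.character(start)) start <- match(start, colnames(X))
  if (is.na(start) || start < 1 || start > p) stop("unknown start variable")
  sel <- integer(k)
  sel[1] <- start
  R <- X # residual columns, orthogonalized in place
  tol <- 1e-8 * max(sqrt(colSums(X^2)))
  live <- rep(TRUE, p)
  for (t in seq_len(k)) {
    if (t > 1) {
      norms <- sqrt(colSums(R^2))
      norms[!live] <- -Inf
      if (max(norms) <= tol) {
        message("SPA chain truncated at ", t - 1,
                " variables (rank deficiency)")
        sel <- sel[seq_len(t - 1)]
        break
      }
      sel[t] <- which.max(norms) # first max = smallest column index on ties
    }
    u <- R[, sel[t]]
    nu <- sum(u^2)
    if (nu > 0) R <- R - u %*% crossprod(u, R) / nu
    live[sel[t]] <- FALSE
  }
  colnames(X)[sel]
}

#' Leave-one-out RMSE of multiple linear regression
#'
#' Closed-form LOO residuals of an ordinary least-squares fit of `y` on the
#' candidate subset (with intercept), via the hat matrix. This is the default
#' evaluator for SPA subset sizing.
#'
#' @param X Numeric matrix of candidate columns.
#' @param y Response vector.
#' @return LOO RMSE, or `NA` when a leverage reaches 1 (saturated fit).
#' @export
loo_rmse_mlr <- function(X, y) {
  X <- as.matrix(X)
  A <- cbind(1, X)
  qr_ <- qr(A)
  if (qr_$rank < ncol(A)) return(NA_real_)
  res <- qr.resid(qr_, y)
  Q <- qr.Q(qr_)
  h <- rowSums(Q^2)
  if (any(h > 1 - 1e-10)) return(NA_real_)
  sqrt(mean((res / (1 - h))^2))
}

#' SPA variable selection
#'
#' Runs the successive projections chain from every candidate start variable
#' and every subset size up to `k_max` and scores each prefix with the
#' evaluator's cross-validated RMSE. The subset is then sized by the
#' criterion in `size_rule`:
#' \describe{
#'   \item{`"ftest"` (default)}{the smallest subset whose RMSE is not
#'     significantly worse than the global minimum under an F test at
#'     `alpha` (the standard SPA parsimony rule); with thousands of
#'     candidate subsets and a few dozen samples, strict minimization
#'     rewards chance fits of uninformative variables, which this rule
#'     suppresses.}
#'   \item{`"min"`}{the strict RMSE minimizer.}
#' }
#' Ties are broken by smaller subset size, then by lexicographic
#' start-variable name, so the result is deterministic and invariant to
#' column order.
#'
#' @param X Design matrix (samples x variables, named columns); standardized
#'   internally.
#' @param y Response vector (LNC, % dry mass).
#' @param k_max Largest subset size to consider; default
#'   `min(10, p, n - 2)`.
#' @param evaluator Function `(X_subset, y) -> RMSE`; default
#'   [loo_rmse_mlr()].
#' @param starts Optional subset of column names to use as chain starts
#'   (default: all columns).
#' @param size_rule `"ftest"` or `"min"`, see above.
#' @param alpha Significance level of the F test (default 0.25).
#' @return An object of class `spa_selection`: list with `selected` (ordered
#'   names), `start`, `k`, `criterion` (RMSE of the chosen subset) and
#'   `rmse_trace` (starts x k matrix of RMSEs).
#' @export
spa_select <- function(X, y, k_max = NULL, evaluator = loo_rmse_mlr,
                       starts = NULL, size_rule = c("ftest", "min"),
                       alpha = 0.25) {
  size_rule <- match.arg(size_rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  Xs <- standardize_columns(X)
  X <- X[, colnames(Xs), drop = FALSE]
  n <- nrow(Xs); p <- ncol(Xs)
  if (n < 4) stop("need at least 4 samples")
  if (is.null(k_max)) k_max <- min(10L, p, n - 2L)
  k_max <- min(k_max, n - 1L, p)
  if (is.null(starts)) starts <- colnames(Xs)
  starts <- sort(intersect(starts, colnames(Xs))) # lexicographic tie order
  if (!length(starts)) stop("no usable start variables")
  trace <- matrix(NA_real_, length(starts), k_max,
                  dimnames = list(starts, paste0("k", seq_len(k_max))))
  chains <- vector("list", length(starts))
  for (si in seq_along(starts)) {
    chain <- spa_chain(Xs, starts[si], k_max)
    chains[[si]] <- chain
    for (k in seq_along(chain)) {
      rmse <- tryCatch(evaluator(X[, chain[seq_len(k)], drop = FALSE], y),
                       error = function(e) NA_real_)
      trace[si, k] <- rmse
    }
  }
  if (all(is.na(trace))) stop("evaluator failed on every candidate subset")
  rmin <- min(trace, na.rm = TRUE)
  cutoff <- if (size_rule == "ftest")
    rmin * sqrt(stats::qf(1 - alpha, n, n)) else rmin
  cutoff <- cutoff + 1e-12 # absolute floor so numerically-zero RMSEs tie
  # admissible subsets; ties -> smaller k, lower RMSE, lexicographic start
  best <- which(trace <= cutoff, arr.ind = TRUE)
  best <- best[order(best[, "col"], trace[best], best[, "row"]), ,
               drop = FALSE][1, ]
  structure(list(selected = chains[[best["row"]]][seq_len(best["col"])],
                 start = starts[best["row"]],
                 k = unname(best["col"]),
                 criterion = trace[best["row"], best["col"]],
                 rmse_trace = trace),
            class = "spa_selection")
}

#' @export
print.spa_selection <- function(x, ...) {
  cat(sprintf("<spa_selection> k = %d (start %s, RMSE %.4g): %s\n",
              x$k, x$start, x$criterion, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' Serialize a selection result to JSON
#' @param sel A `spa_selection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_selection <- function(sel, path) {
  jsonlite::write_json(
    list(selected = sel$selected, start = sel$start, k = sel$k,
         criterion = sel$criterion,
         rmse_trace = as.data.frame(sel$rmse_trace)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
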