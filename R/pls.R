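# Single-response partial least squares (PLS1) by NIPALS, with inner
# cross-validated selection of the number of latent components.

#' Fit a single-response PLS regression model
#'
#' NIPALS PLS1 on column-standardized predictors (unit-variance scaling with
#' means and scales taken from the calibration data passed in). Regression
#' coefficients are mapped back to the original predictor scale so that
#' `predict(model, X)` is `intercept + X %*% coefficients`.
#'
#' @param X Numeric matrix (samples x variables), no missing values.
#' @param y Numeric response vector.
#' @param n_components Number of latent components (>= 1). Truncated with a
#'   warning if it exceeds the rank of the calibration matrix.
#' @return An object of class `pls_model` with elements `coefficients`,
#'   `intercept`, `n_components`, `x_means`, `x_scales`, and
#'   `coefficient_path` (coefficients for every component count up to the
#'   fitted one, one column per count).
#' @export
fit_pls <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) rlang::abort("missing values are not allowed")
  if (n_components < 1) rlang::abort("n_components must be >= 1")
  n <- nrow(X); p <- ncol(X)
  mx <- colMeans(X)
  sx <- apply(X, 2, stats::sd)
  if (any(sx == 0)) {
    rlang::abort(paste0("zero-variance columns: ",
                        paste(colnames(X)[sx == 0], collapse = ", ")))
  }
  E <- sweep(sweep(X, 2, mx, "-"), 2, sx, "/")
  my <- mean(y)
  f <- y - my
  A <- min(n_components, p, n - 1)
  W <- matrix(0, p, A); P <- matrix(0, p, A); Q <- numeric(A)
  a <- 0L
  for (k in seq_len(A)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break
    w <- w / wn
    t <- as.numeric(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- as.numeric(crossprod(E, t)) / tt
    q <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - q * t
    a <- k
    W[, k] <- w; P[, k] <- pl; Q[k] <- q
  }
  if (a == 0L) rlang::abort("no usable PLS component (response orthogonal to predictors)")
  if (a < n_components && n_components <= min(p, n - 1)) {
    rlang::warn(sprintf("n_components truncated from %d to %d (rank limit)",
                        n_components, a))
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  Q <- Q[seq_len(a)]
  # coefficients on the standardized scale for every component count <= a
  path <- matrix(0, p, a)
  PtW <- crossprod(P, W)  # upper triangular with unit-ish diagonal
  for (k in seq_len(a)) {
    rk <- solve(PtW[seq_len(k), seq_len(k), drop = FALSE], Q[seq_len(k)])
    path[, k] <- W[, seq_len(k), drop = FALSE] %*% rk
  }
  path <- sweep(path, 1, sx, "/")  # back to original predictor scale
  rownames(path) <- colnames(X)
  coefs <- path[, a]
  structure(list(coefficients = coefs,
                 intercept = my - sum(mx * coefs),
                 n_components = a,
                 x_means = mx, x_scales = sx, y_mean = my,
                 coefficient_path = path),
            class = "pls_model")
}

#' @export
predict.pls_model <- function(object, newdata, n_components = NULL, ...) {
  X <- as.matrix(newdata)
  b <- if (is.null(n_components)) object$coefficients else {
    k <- min(n_components, object$n_components)
    object$coefficient_path[, k]
  }
  intercept <- object$y_mean - sum(object$x_means * b)
  as.numeric(intercept + X %*% b)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d components, %d predictors\n",
              x$n_components, length(x$coefficients)))
  invisible(x)
}

#' Tune the number of PLS components by inner cross-validation
#'
#' A single random `inner_folds`-fold assignment (from the current RNG
#' state) is used; the component count minimizing cross-validated RMSE over
#' 1..`max_components` is returned, smallest count on ties. The count is
#' capped at `max_components` even when the RMSE is still decreasing.
#'
#' @param X_cal,y_cal Calibration data.
#' @param inner_folds Number of folds (default 8).
#' @param max_components Upper bound on the component count (default 10).
#' @return List with `n_components` and `rmse` (per candidate count).
#' @export
tune_ncomp <- function(X_cal, y_cal, inner_folds = 8, max_components = 10) {
  X_cal <- as.matrix(X_cal)
  n <- nrow(X_cal)
  if (n < inner_folds) rlang::abort("calibration set smaller than the fold count")
  kmax <- min(max_components, ncol(X_cal),
              n - ceiling(n / inner_folds) - 1)
  kmax <- max(kmax, 1)
  folds <- sample(rep(seq_len(inner_folds), length.out = n))
  sse <- numeric(kmax)
  cnt <- numeric(kmax)
  for (fd in seq_len(inner_folds)) {
    hold <- folds == fd
    fit <- fit_pls(X_cal[!hold, , drop = FALSE], y_cal[!hold], kmax)
    for (k in seq_len(min(kmax, fit$n_components))) {
      pred <- predict(fit, X_cal[hold, , drop = FALSE], n_components = k)
      sse[k] <- sse[k] + sum((y_cal[hold] - pred)^2)
      cnt[k] <- cnt[k] + sum(hold)
    }
  }
  usable <- cnt > 0
  rmse <- rep(Inf, kmax)
  rmse[usable] <- sqrt(sse[usable] / cnt[usable])
  list(n_components = which.min(rmse), rmse = rmse)
}
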