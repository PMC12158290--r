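# Calibration models: random train/validation split, two-band ordinary
# least squares, NIPALS PLS1, and the R^2 / RMSE evaluation metrics
#
#   R^2  = 1 - sum((CHL - CHLP)^2) / sum((CHL - mean(CHL))^2)
#   RMSE = sqrt(mean((CHL - CHLP)^2))
#
# where CHL is the measured and CHLP the model-estimated SPAD value.

#' Random train/validation split
#'
#' @param n_total Total sample count.
#' @param n_train,n_valid Group sizes; must sum to `n_total`, and at least
#'   one validation sample is required.
#' @param seed Integer seed; the assignment is deterministic per seed.
#' @return A `split_spec` list with `train_idx`, `valid_idx`, an
#'   `assignment` factor and the seed used.
#' @export
split_samples <- function(n_total, n_train = 60L, n_valid = 27L,
                          seed = 20250605L) {
  if (n_train + n_valid != n_total) {
    stop(sprintf("n_train (%d) + n_valid (%d) != n_total (%d)",
                 n_train, n_valid, n_total), call. = FALSE)
  }
  if (n_valid < 1L) stop("a validation group is required", call. = FALSE)
  train_idx <- withr::with_seed(seed, sort(sample.int(n_total, n_train)))
  valid_idx <- setdiff(seq_len(n_total), train_idx)
  assignment <- factor(ifelse(seq_len(n_total) %in% train_idx,
                              "train", "valid"),
                       levels = c("train", "valid"))
  structure(list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 seed = as.integer(seed), train_idx = train_idx,
                 valid_idx = valid_idx, assignment = assignment),
            class = "split_spec")
}

standardize_cols <- function(x, center, scale) {
  sweep(sweep(x, 2L, center, "-"), 2L, scale, "/")
}

new_spad_model <- function(method, bands_nm, intercept, coefficients,
                           x_center, x_scale, y_center, y_scale,
                           standardized, transform_tag = NA_character_,
                           n_components = NA_integer_) {
  # coefficients on the original predictor scale, for reporting
  b_raw <- coefficients * y_scale / x_scale
  structure(list(
    method = method, transform_tag = transform_tag,
    bands_nm = bands_nm, intercept = intercept, coefficients = coefficients,
    standardized = standardized, n_components = n_components,
    x_center = x_center, x_scale = x_scale,
    y_center = y_center, y_scale = y_scale,
    coefficients_raw = b_raw,
    intercept_raw = y_center + intercept * y_scale - sum(b_raw * x_center)
  ), class = "spad_model")
}

#' Two-band ordinary least squares calibration
#'
#' Fits `y = b0 + b1 x_band1 + b2 x_band2`. With `standardize = TRUE`
#' (the default) predictors and response are z-scored on the training
#' data, so coefficients are in standardized units; raw-unit coefficients
#' are kept alongside, and predictions are always in SPAD units.
#'
#' @param x Numeric matrix, samples by 2 predictor bands; column names are
#'   band labels.
#' @param y SPAD responses.
#' @param standardize Z-score predictors and response before fitting.
#' @param transform_tag Tag recorded on the model.
#' @return A `spad_model`.
#' @export
fit_two_band <- function(x, y, standardize = TRUE,
                         transform_tag = NA_character_) {
  x <- as.matrix(x)
  if (ncol(x) != 2L) stop("exactly 2 predictor bands required", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 training samples", call. = FALSE)
  if (length(y) != nrow(x)) stop("y must match rows of x", call. = FALSE)
  bands <- colnames(x)
  if (is.null(bands)) bands <- paste0("b", seq_len(ncol(x)))
  if (qr(cbind(1, x))$rank < 3L) {
    stop("collinear predictor bands: ", paste(bands, collapse = ", "),
         call. = FALSE)
  }
  if (standardize) {
    xc <- colMeans(x); xs <- apply(x, 2L, stats::sd)
    yc <- mean(y); ys <- stats::sd(y)
    if (ys == 0) { yc <- mean(y); ys <- 1 }
  } else {
    xc <- rep(0, 2L); xs <- rep(1, 2L); yc <- 0; ys <- 1
  }
  xst <- standardize_cols(x, xc, xs)
  yst <- (y - yc) / ys
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, xst), yst)
  cf <- fit$coefficients
  new_spad_model("two_band_ols", bands, unname(cf[1]), unname(cf[-1]),
                 xc, xs, yc, ys, standardize, transform_tag)
}

#' NIPALS partial least squares (PLS1) calibration
#'
#' Classical NIPALS for a univariate response: predictors (and response)
#' are centered — and scaled when `standardize = TRUE` — then weight,
#' score and loading vectors are extracted component by component with
#' deflation. With a single response the NIPALS inner loop reaches its
#' fixed point `w = E'f / ||E'f||` in one pass, so each component is
#' evaluated in closed form. The final model is composed into affine
#' coefficients `B = W (P'W)^{-1} q`, so prediction is a single matrix
#' product.
#'
#' @param x Numeric matrix, samples by predictor bands.
#' @param y SPAD responses.
#' @param n_components Number of latent components, between 1 and the rank
#'   of the centered predictor matrix.
#' @param standardize Z-score predictors and response (centering always
#'   happens).
#' @param transform_tag Tag recorded on the model.
#' @param tol Threshold below which the residual covariance `||E'f||` is
#'   treated as exhausted (the extraction is rejected with diagnostics).
#' @return A `spad_model` with `method = "pls"`.
#' @export
fit_pls <- function(x, y, n_components, standardize = TRUE,
                    transform_tag = NA_character_, tol = 1e-12) {
  x <- as.matrix(x)
  if (nrow(x) != length(y)) stop("y must match rows of x", call. = FALSE)
  bands <- colnames(x)
  if (is.null(bands)) bands <- paste0("b", seq_len(ncol(x)))
  xc <- colMeans(x)
  xs <- if (standardize) apply(x, 2L, stats::sd) else rep(1, ncol(x))
  if (any(xs == 0)) {
    stop("zero-variance predictor band(s): ",
         paste(bands[xs == 0], collapse = ", "), call. = FALSE)
  }
  yc <- mean(y)
  ys <- if (standardize) stats::sd(y) else 1
  if (ys == 0) ys <- 1
  E <- standardize_cols(x, xc, xs)
  f <- (y - yc) / ys
  r <- qr(E)$rank
  if (n_components < 1L || n_components > r) {
    stop(sprintf("n_components = %d outside [1, rank = %d]", n_components, r),
         call. = FALSE)
  }
  p <- ncol(x)
  W <- P <- matrix(0, p, n_components)
  Q <- numeric(n_components)
  for (k in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < tol) {
      stop(sprintf("covariance with the response exhausted at component %d (||E'f|| = %.3g)",
                   k, nw), call. = FALSE)
    }
    w <- w / nw
    tt <- drop(E %*% w)
    q <- sum(f * tt) / sum(tt^2)
    pk <- drop(crossprod(E, tt)) / sum(tt^2)
    W[, k] <- w; P[, k] <- pk; Q[k] <- q
    E <- E - tcrossprod(tt, pk)
    f <- f - tt * q
  }
  B <- drop(W %*% solve(crossprod(P, W), Q))
  new_spad_model("pls", bands, 0, B, xc, xs, yc, ys, standardize,
                 transform_tag, as.integer(n_components))
}

#' Predict SPAD from a fitted calibration model
#'
#' @param object A `spad_model`.
#' @param newdata Samples-by-bands matrix with the model's predictor
#'   columns.
#' @param ... Unused.
#' @return Predicted SPAD values (original units).
#' @export
predict.spad_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$coefficients)) {
    stop("newdata must have one column per model band", call. = FALSE)
  }
  xs <- standardize_cols(newdata, object$x_center, object$x_scale)
  yst <- object$intercept + drop(xs %*% object$coefficients)
  yst * object$y_scale + object$y_center
}

#' @export
print.spad_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4g x_%s", x$coefficients_raw, x$bands_nm),
                 collapse = " ")
  cat(sprintf("<spad_model %s%s> y = %.4g %s\n", x$method,
              if (!is.na(x$n_components)) paste0(", ", x$n_components, " comp")
              else "", x$intercept_raw, terms))
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken around the mean of the
#' measured values. May be negative on a validation set.
#'
#' @param measured,predicted Equal-length numeric vectors (length >= 2);
#'   `measured` must not be constant.
#' @return A single number <= 1.
#' @export
r_squared <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) < 2) {
    stop("measured and predicted must be equal-length, length >= 2",
         call. = FALSE)
  }
  ss_tot <- sum((measured - mean(measured))^2)
  if (ss_tot == 0) stop("measured values are constant; R^2 undefined",
                        call. = FALSE)
  1 - sum((measured - predicted)^2) / ss_tot
}

#' Root mean square error
#'
#' @param measured,predicted Equal-length, non-empty numeric vectors.
#' @return `sqrt(mean((measured - predicted)^2))`, SPAD units.
#' @export
rmse <- function(measured, predicted) {
  if (length(measured) == 0 || length(measured) != length(predicted)) {
    stop("measured and predicted must be equal-length and non-empty",
         call. = FALSE)
  }
  sqrt(mean((measured - predicted)^2))
}

#' Choose the PLS component count by leave-one-out RMSE
#'
#' @param x Training predictor matrix.
#' @param y Training responses.
#' @param max_components Upper bound (capped at the design rank).
#' @param standardize Passed through to [fit_pls()].
#' @return The component count minimizing leave-one-out RMSE.
#' @export
choose_pls_ncomp <- function(x, y, max_components = ncol(x),
                             standardize = TRUE) {
  x <- as.matrix(x)
  r <- qr(scale(x, scale = FALSE))$rank
  kmax <- min(max_components, r)
  loo <- vapply(seq_len(kmax), function(k) {
    preds <- vapply(seq_len(nrow(x)), function(i) {
      m <- fit_pls(x[-i, , drop = FALSE], y[-i], k, standardize)
      predict(m, x[i, , drop = FALSE])
    }, numeric(1))
    rmse(y, preds)
  }, numeric(1))
  which.min(loo)
}
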