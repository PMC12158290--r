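# End-to-end orchestration: window -> smooth -> transform -> correlate ->
# select bands -> fit -> evaluate, over any subset of the 12 transforms.

#' Pipeline configuration
#'
#' @param window_nm Analysis wavelength window, `c(min, max)` nm. The
#'   default 400-1075 nm covers the chlorophyll absorption and red-edge
#'   region while trimming the noisiest spectrometer edges.
#' @param smoothing A [smoothing_params()].
#' @param transforms Subset of [transform_tags()] to run.
#' @param k_bands Sensitive bands per model (default 2).
#' @param min_separation_nm Minimum distance between selected bands.
#' @param n_train,n_valid Split sizes.
#' @param split_seed Seed for the random split.
#' @param method `"pls"` (the default: NIPALS PLS on the selected bands,
#'   component count chosen by leave-one-out RMSE unless `pls_components`
#'   is given, and capped at the design rank) or `"two_band_ols"` (the
#'   two-band affine model matching the classical reporting style; note
#'   that on noiseless data any two bands are exactly collinear and OLS is
#'   rejected as unidentifiable, whereas PLS degrades gracefully to one
#'   component).
#' @param pls_components Fixed PLS component count, or `NULL` for
#'   leave-one-out selection.
#' @param standardize Z-score predictors and response on the training
#'   split before fitting.
#' @param correlate_on `"train"` computes the band screen on the modeling
#'   split only (the honest default); `"all"` uses every sample.
#' @param clip_floor Floor for `1/R` and `log10 R`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(window_nm = c(400, 1075),
                            smoothing = smoothing_params(),
                            transforms = transform_tags(),
                            k_bands = 2L,
                            min_separation_nm = 50,
                            n_train = 60L,
                            n_valid = 27L,
                            split_seed = 20250605L,
                            method = c("pls", "two_band_ols"),
                            pls_components = NULL,
                            standardize = TRUE,
                            correlate_on = c("train", "all"),
                            clip_floor = 1e-4) {
  method <- match.arg(method)
  correlate_on <- match.arg(correlate_on)
  bad <- setdiff(transforms, transform_tags())
  if (length(bad)) {
    stop("unknown transform tag(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(window_nm = window_nm, smoothing = smoothing,
                 transforms = transforms, dwt_levels = 3L,
                 k_bands = as.integer(k_bands),
                 min_separation_nm = min_separation_nm,
                 n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                 split_seed = as.integer(split_seed), method = method,
                 pls_components = pls_components, standardize = standardize,
                 correlate_on = correlate_on, clip_floor = clip_floor),
            class = "pipeline_config")
}

#' Run the full SPAD estimation pipeline
#'
#' For every requested transform: build the representation of the
#' smoothed, windowed spectra, screen bands by Pearson correlation with
#' SPAD on the modeling split, select the sensitive bands, fit the
#' calibration model, and evaluate R^2 / RMSE on both splits. The winner
#' is the model with the highest validation R^2 (ties broken by lower
#' validation RMSE).
#'
#' @param dataset A labelled [spectra_set()].
#' @param config A [pipeline_config()].
#' @return A `spad_pipeline_result`: `comparison` (one tibble row per
#'   transform with bands, model text and the four metrics), `winner_tag`,
#'   `models`, `profiles`, `selections`, `predictions` (per-transform
#'   measured/predicted/split tibbles) and the `split` used.
#' @export
run_pipeline <- function(dataset, config = pipeline_config()) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (!inherits(config, "pipeline_config")) {
    stop("`config` must come from pipeline_config()", call. = FALSE)
  }
  if (anyNA(dataset$samples$spad)) {
    stop("every sample needs a SPAD label", call. = FALSE)
  }
  ds <- window_dataset(dataset, config$window_nm)
  ds <- smooth_spectra(ds, config$smoothing)
  n <- n_samples(ds)
  spad <- ds$samples$spad
  split <- split_samples(n, config$n_train, config$n_valid, config$split_seed)
  needs_dwt <- any(config$transforms %in% c("L1", "L2", "L3", "H1", "H2", "H3"))
  dwt <- if (needs_dwt) haar_dwt_set(ds, config$dwt_levels) else NULL

  models <- profiles <- selections <- predictions <- list()
  rows <- vector("list", length(config$transforms))
  for (ti in seq_along(config$transforms)) {
    tag <- config$transforms[ti]
    step <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("[%s/%s] %s", tag, what, conditionMessage(e)),
             call. = FALSE)
      })
    }
    rep <- step("transform", build_representation(ds, tag, config$clip_floor, dwt))
    cidx <- if (config$correlate_on == "train") split$train_idx else seq_len(n)
    prof <- step("correlate",
                 correlate(rep$values[, cidx, drop = FALSE], spad[cidx],
                           rep$axis_nm, tag))
    sel <- step("select", select_bands(prof, config$k_bands,
                                       config$min_separation_nm))
    bi <- match(sel$bands_nm, rep$axis_nm)
    X <- t(rep$values[bi, , drop = FALSE])
    colnames(X) <- format_band(sel$bands_nm)
    Xtr <- X[split$train_idx, , drop = FALSE]
    Xva <- X[split$valid_idx, , drop = FALSE]
    ytr <- spad[split$train_idx]
    yva <- spad[split$valid_idx]
    model <- step("fit", {
      if (config$method == "two_band_ols") {
        fit_two_band(Xtr, ytr, config$standardize, tag)
      } else {
        k <- config$pls_components
        if (is.null(k)) k <- choose_pls_ncomp(Xtr, ytr,
                                              standardize = config$standardize)
        fit_pls(Xtr, ytr, k, config$standardize, tag)
      }
    })
    ptr <- predict(model, Xtr)
    pva <- predict(model, Xva)
    rows[[ti]] <- tibble::tibble(
      transform_tag = tag,
      bands_nm = paste(format_band(sel$bands_nm), collapse = ", "),
      model = format(model_equation(model)),
      r2_train = r_squared(ytr, ptr), rmse_train = rmse(ytr, ptr),
      r2_valid = r_squared(yva, pva), rmse_valid = rmse(yva, pva))
    models[[tag]] <- model
    profiles[[tag]] <- prof
    selections[[tag]] <- sel
    predictions[[tag]] <- tibble::tibble(
      sample_id = ds$samples$sample_id,
      split = split$assignment,
      measured = spad,
      predicted = c(predict(model, X)))
  }
  comparison <- do.call(rbind, rows)
  win <- order(-comparison$r2_valid, comparison$rmse_valid)[1]
  structure(list(comparison = comparison,
                 winner_tag = comparison$transform_tag[win],
                 models = models, profiles = profiles,
                 selections = selections, predictions = predictions,
                 split = split, config = config),
            class = "spad_pipeline_result")
}

format_band <- function(x) {
  ifelse(abs(x - round(x)) < 1e-9, sprintf("%d", round(x)),
         sprintf("%.1f", x))
}

model_equation <- function(model) {
  terms <- paste(sprintf("%+.3f x_%s", model$coefficients_raw,
                         model$bands_nm), collapse = " ")
  sprintf("y = %.3f %s", model$intercept_raw, terms)
}

#' @export
print.spad_pipeline_result <- function(x, ...) {
  cat("<spad_pipeline_result>\n")
  print(x$comparison, n = Inf)
  cat(sprintf("winner: %s (validation R^2 = %.3f, RMSE = %.3f)\n",
              x$winner_tag,
              x$comparison$r2_valid[x$comparison$transform_tag == x$winner_tag],
              x$comparison$rmse_valid[x$comparison$transform_tag == x$winner_tag]))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' @param model A `spad_model`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "spad_model"))
  jsonlite::write_json(list(
    method = model$method, transform_tag = model$transform_tag,
    bands_nm = model$bands_nm, intercept = model$intercept,
    coefficients = model$coefficients, standardized = model$standardized,
    n_components = model$n_components,
    x_center = model$x_center, x_scale = model$x_scale,
    y_center = model$y_center, y_scale = model$y_scale,
    intercept_raw = model$intercept_raw,
    coefficients_raw = model$coefficients_raw
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
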