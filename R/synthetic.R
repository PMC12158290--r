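# Synthetic leaf-spectra generator: the statistical stand-in for a field
# campaign of canopy leaves measured with a 350-2500 nm spectroradiometer
# and a transmittance SPAD meter.

#' Configuration for the synthetic spectra generator
#'
#' Defines the study conditions the generator emulates: 87 canopy leaves in
#' four compass directions, SPAD values following a truncated normal with
#' the campaign's summary statistics, chlorophyll absorption wells in the
#' blue (~450 nm) and red (~670 nm), a logistic red edge near 715 nm,
#' smooth sample-to-sample baseline drift, and independent per-band
#' high-frequency "dust" noise.
#'
#' @param n_samples Number of leaf samples.
#' @param direction_counts Named integer vector of per-direction sample
#'   counts (`east`, `south`, `west`, `north`); must sum to `n_samples`.
#' @param spad_mean,spad_sd Mean and SD of the latent SPAD distribution.
#' @param spad_min,spad_max Truncation bounds for SPAD (SPAD units).
#' @param feature_bands Data frame with columns `center_nm`, `width_nm`
#'   (Gaussian sigma) and `sensitivity` (well depth in reflectance units
#'   per SPAD unit). Each well's depth is `sensitivity * SPAD`.
#' @param red_edge_center_nm,red_edge_width_nm Center and logistic scale of
#'   the red-edge reflectance rise.
#' @param baseline_visible,baseline_nir Continuum reflectance below and
#'   above the red edge.
#' @param smooth_noise_sd Scale of the smooth (low-order polynomial)
#'   baseline perturbation, reflectance units.
#' @param dust_noise_sd SD of i.i.d. per-band additive noise, reflectance
#'   units. This is the pure high-frequency component that a wavelet
#'   decomposition pushes into the detail series.
#' @param spad_meter_error_sd SD of the SPAD meter reading error applied to
#'   the recorded (not the latent) SPAD value.
#' @param wavelength_nm Strictly increasing, uniformly spaced grid.
#' @param seed Integer seed governing all randomness in the generator.
#'
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 87L,
                             direction_counts = c(east = 22L, south = 22L,
                                                  west = 22L, north = 21L),
                             spad_mean = 45.8,
                             spad_sd = 3.64,
                             spad_min = 32.6,
                             spad_max = 67.1,
                             feature_bands = data.frame(
                               center_nm = c(450, 670),
                               width_nm = c(40, 30),
                               sensitivity = c(0.0012, 0.0012)),
                             red_edge_center_nm = 715,
                             red_edge_width_nm = 15,
                             baseline_visible = 0.10,
                             baseline_nir = 0.45,
                             smooth_noise_sd = 0.003,
                             dust_noise_sd = 0.002,
                             spad_meter_error_sd = 0.5,
                             wavelength_nm = 350:2500,
                             seed = 1L) {
  cfg <- structure(list(
    n_samples = as.integer(n_samples),
    direction_counts = direction_counts,
    spad_mean = spad_mean, spad_sd = spad_sd,
    spad_min = spad_min, spad_max = spad_max,
    feature_bands = feature_bands,
    red_edge_center_nm = red_edge_center_nm,
    red_edge_width_nm = red_edge_width_nm,
    baseline_visible = baseline_visible,
    baseline_nir = baseline_nir,
    smooth_noise_sd = smooth_noise_sd,
    dust_noise_sd = dust_noise_sd,
    spad_meter_error_sd = spad_meter_error_sd,
    wavelength_nm = as.numeric(wavelength_nm),
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  if (!inherits(cfg, "synthetic_config")) {
    stop("`config` must be created by synthetic_config()", call. = FALSE)
  }
  wl <- cfg$wavelength_nm
  if (length(wl) < 8) {
    stop("wavelength grid must have at least 8 bands ",
         "(a 3-level dyadic decomposition needs 3 halvings)", call. = FALSE)
  }
  d <- diff(wl)
  if (any(d <= 0) || diff(range(d)) > 1e-9) {
    stop("wavelength grid must be strictly increasing and uniformly spaced",
         call. = FALSE)
  }
  if (sum(cfg$direction_counts) != cfg$n_samples) {
    stop(sprintf("direction_counts sum to %d but n_samples is %d",
                 sum(cfg$direction_counts), cfg$n_samples), call. = FALSE)
  }
  if (!(cfg$spad_min < cfg$spad_mean && cfg$spad_mean < cfg$spad_max)) {
    stop("require spad_min < spad_mean < spad_max", call. = FALSE)
  }
  sds <- c(cfg$spad_sd, cfg$smooth_noise_sd, cfg$dust_noise_sd,
           cfg$spad_meter_error_sd)
  if (any(sds < 0)) stop("noise standard deviations must be >= 0", call. = FALSE)
  fb <- cfg$feature_bands
  if (!all(c("center_nm", "width_nm", "sensitivity") %in% names(fb))) {
    stop("feature_bands needs columns center_nm, width_nm, sensitivity",
         call. = FALSE)
  }
  bad <- fb$center_nm < min(wl) | fb$center_nm > max(wl)
  if (any(bad)) {
    stop(sprintf("feature band center(s) outside the wavelength grid: %s",
                 paste(fb$center_nm[bad], collapse = ", ")), call. = FALSE)
  }
  invisible(cfg)
}

# Truncated normal by rejection; valid because the bounds bracket the mean
# (checked by the config validator), so acceptance probability is >= 1/2.
rtruncnorm_reject <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic spectra + SPAD dataset
#'
#' Reflectance is built additively: a logistic red-edge continuum, minus
#' Gaussian absorption wells whose depths scale linearly with the sample's
#' latent SPAD, plus a smooth low-order polynomial perturbation, plus
#' independent per-band dust noise; the result is clipped to \[0, 1\]. The
#' recorded SPAD is the latent value perturbed by meter error and clamped
#' to the configured bounds. The planted truth (latent SPAD, well centers
#' and sensitivities) is kept in the returned object for recovery tests.
#'
#' @param config A [synthetic_config()].
#' @return A [spectra_set()] with `truth` filled in.
#' @export
generate_dataset <- function(config) {
  validate_synthetic_config(config)
  withr::with_seed(config$seed, {
    wl <- config$wavelength_nm
    n <- config$n_samples
    nb <- length(wl)

    spad_true <- rtruncnorm_reject(n, config$spad_mean, config$spad_sd,
                                   config$spad_min, config$spad_max)
    spad <- spad_true + stats::rnorm(n, 0, config$spad_meter_error_sd)
    spad <- pmin(pmax(spad, config$spad_min), config$spad_max)

    baseline <- config$baseline_visible +
      (config$baseline_nir - config$baseline_visible) *
      stats::plogis((wl - config$red_edge_center_nm) / config$red_edge_width_nm)

    fb <- config$feature_bands
    well_shape <- vapply(seq_len(nrow(fb)), function(i) {
      exp(-(wl - fb$center_nm[i])^2 / (2 * fb$width_nm[i]^2))
    }, numeric(nb))

    # Chebyshev T0..T3 basis for the smooth, spatially correlated drift.
    u <- 2 * (wl - wl[1]) / (wl[nb] - wl[1]) - 1
    cheb <- cbind(1, u, 2 * u^2 - 1, 4 * u^3 - 3 * u)

    refl <- matrix(NA_real_, nb, n)
    for (i in seq_len(n)) {
      wells <- drop(well_shape %*% (fb$sensitivity * spad_true[i]))
      drift <- drop(cheb %*% stats::rnorm(4)) * config$smooth_noise_sd / 2
      dust <- stats::rnorm(nb, 0, config$dust_noise_sd)
      refl[, i] <- pmin(pmax(baseline - wells + drift + dust, 0), 1)
    }

    ids <- sprintf("S%03d", seq_len(n))
    colnames(refl) <- ids
    directions <- rep(names(config$direction_counts), config$direction_counts)

    spectra_set(
      wavelength_nm = wl,
      reflectance = refl,
      samples = tibble::tibble(sample_id = ids, direction = directions,
                               spad = spad),
      truth = list(
        spad_true = spad_true,
        feature_bands = fb,
        red_edge_center_nm = config$red_edge_center_nm,
        baseline_visible = config$baseline_visible,
        baseline_nir = config$baseline_nir
      )
    )
  })
}

#' Construct a spectra set
#'
#' The pipeline's central container: a bands-by-samples reflectance matrix
#' on a shared uniform wavelength grid, plus an order-aligned sample table
#' with direction and SPAD labels.
#'
#' @param wavelength_nm Strictly increasing, uniformly spaced numeric grid.
#' @param reflectance Numeric matrix, `length(wavelength_nm)` rows, one
#'   column per sample; column names are sample ids.
#' @param samples Tibble with columns `sample_id`, `direction`, `spad`
#'   (spad may be `NA` when labels are not yet joined).
#' @param truth Optional list recording generating parameters.
#' @return A `spectra_set`.
#' @export
spectra_set <- function(wavelength_nm, reflectance, samples, truth = NULL) {
  reflectance <- as.matrix(reflectance)
  if (nrow(reflectance) != length(wavelength_nm)) {
    stop("reflectance must have one row per wavelength", call. = FALSE)
  }
  if (ncol(reflectance) != nrow(samples)) {
    stop("one sample row per spectrum required", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (anyNA(reflectance)) stop("reflectance contains missing values", call. = FALSE)
  d <- diff(wavelength_nm)
  if (length(wavelength_nm) > 1 && (any(d <= 0) || diff(range(d)) > 1e-9)) {
    stop("wavelength grid must be strictly increasing and uniform", call. = FALSE)
  }
  structure(list(wavelength_nm = as.numeric(wavelength_nm),
                 reflectance = reflectance,
                 samples = samples,
                 truth = truth),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d bands (%g-%g nm)\n",
              ncol(x$reflectance), length(x$wavelength_nm),
              min(x$wavelength_nm), max(x$wavelength_nm)))
  sp <- x$samples$spad
  if (!all(is.na(sp))) {
    cat(sprintf("  SPAD: mean %.1f sd %.2f range [%.1f, %.1f]\n",
                mean(sp, na.rm = TRUE), stats::sd(sp, na.rm = TRUE),
                min(sp, na.rm = TRUE), max(sp, na.rm = TRUE)))
  }
  invisible(x)
}

#' Number of samples in a spectra set
#' @param dataset A `spectra_set`.
#' @return Integer count.
#' @export
n_samples <- function(dataset) ncol(dataset$reflectance)
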