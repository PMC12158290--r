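# Classical spectral transforms: 1/R, log10(R) and central-difference
# first derivatives. All operate on a bands-by-samples value matrix (or a
# plain vector) and return values on the same scale conventions used for
# band screening downstream.

#' The twelve transform tags the pipeline knows
#'
#' `R`, `invR`, `logR` are pointwise transforms of the smoothed spectrum;
#' `dR`, `d_invR`, `d_logR` their central-difference first derivatives;
#' `L1`-`L3` and `H1`-`H3` the approximation and detail series of the
#' 3-level Haar decomposition.
#'
#' @return Character vector of the 12 tags.
#' @export
transform_tags <- function() {
  c("R", "invR", "logR", "dR", "d_invR", "d_logR",
    "L1", "L2", "L3", "H1", "H2", "H3")
}

clip_reflectance <- function(x, clip_floor) {
  n_clipped <- sum(x < clip_floor)
  if (n_clipped > 0) {
    # field spectra can dip <= 0 near the grid edges after smoothing
    attr_x <- pmax(x, clip_floor)
  } else {
    attr_x <- x
  }
  attr(attr_x, "n_clipped") <- n_clipped
  attr_x
}

#' Inverse reflectance transform (1/R)
#'
#' @param x Reflectance vector or bands-by-samples matrix.
#' @param clip_floor Values below this are raised to it before inversion,
#'   so zeros never produce infinities; the count of clipped cells is kept
#'   in the `"n_clipped"` attribute.
#' @return `1 / pmax(x, clip_floor)`, same shape as `x`.
#' @export
inverse_reflectance <- function(x, clip_floor = 1e-4) {
  xc <- clip_reflectance(x, clip_floor)
  out <- 1 / xc
  attr(out, "n_clipped") <- attr(xc, "n_clipped")
  if (attr(out, "n_clipped") == length(x)) {
    warning("all values at or below clip_floor; result is constant",
            call. = FALSE)
  }
  out
}

#' Logarithmic reflectance transform (log10 R)
#'
#' @inheritParams inverse_reflectance
#' @return `log10(pmax(x, clip_floor))`, same shape as `x`.
#' @export
log_reflectance <- function(x, clip_floor = 1e-4) {
  xc <- clip_reflectance(x, clip_floor)
  out <- log10(xc)
  attr(out, "n_clipped") <- attr(xc, "n_clipped")
  if (attr(out, "n_clipped") == length(x)) {
    warning("all values at or below clip_floor; result is constant",
            call. = FALSE)
  }
  out
}

#' First derivative of a spectral series
#'
#' Central differences `(v[i+1] - v[i-1]) / (2 * delta)` on a uniform
#' axis; the two endpoints are dropped, so the axis shortens by 2.
#'
#' @param values Vector or bands-by-samples matrix.
#' @param axis_nm Uniform, strictly increasing wavelength axis matching
#'   the rows of `values`.
#' @return List with `values` (same type as input, 2 bands shorter) and
#'   `axis_nm`.
#' @export
first_derivative <- function(values, axis_nm) {
  v <- if (is.matrix(values)) values else matrix(values, ncol = 1L)
  n <- nrow(v)
  if (n < 3L) stop("need at least 3 bands for a central difference",
                   call. = FALSE)
  if (length(axis_nm) != n) stop("axis length must match values", call. = FALSE)
  d <- diff(axis_nm)
  if (diff(range(d)) > 1e-9) stop("axis must be uniformly spaced", call. = FALSE)
  delta <- d[1]
  out <- (v[3:n, , drop = FALSE] - v[1:(n - 2L), , drop = FALSE]) / (2 * delta)
  if (!is.matrix(values)) out <- drop(out)
  list(values = out, axis_nm = axis_nm[2:(n - 1L)])
}
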