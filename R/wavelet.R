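# Multi-level orthonormal Haar discrete wavelet decomposition.
#
# At each level the current approximation is split into pairwise
# orthonormal sums (approximation, low-frequency L) and differences
# (detail, high-frequency H):
#
#   a[i] = (x[2i-1] + x[2i]) / sqrt(2),  d[i] = (x[2i-1] - x[2i]) / sqrt(2)
#
# so Parseval holds exactly at every level. Odd lengths are reflect-padded
# by one sample (the last value repeated); pad positions are excluded from
# the coefficient-to-wavelength mapping, which assigns each coefficient
# the mean of the original wavelengths in its support.

#' Multi-level Haar discrete wavelet transform
#'
#' @param x Numeric value series (one spectrum), length at least
#'   `2^levels`.
#' @param wavelengths_nm Wavelength per value, same length as `x`.
#' @param levels Number of dyadic decomposition levels (default 3).
#' @return A `haar_decomposition`: lists `approximations` and `details`
#'   indexed by level, each entry holding `values` and `axis_nm`
#'   (support-midpoint wavelengths), plus `pad_length`, the total count of
#'   boundary values appended across levels, and `input_ss`, the squared
#'   sum of the input for energy checks.
#' @export
haar_dwt <- function(x, wavelengths_nm = seq_along(x), levels = 3L) {
  levels <- as.integer(levels)
  n <- length(x)
  if (length(wavelengths_nm) != n) {
    stop("wavelengths_nm must match the value series length", call. = FALSE)
  }
  if (n < 2^levels) {
    stop(sprintf("series of length %d too short for %d dyadic halvings (need >= %d)",
                 n, levels, 2^levels), call. = FALSE)
  }
  cur <- as.numeric(x)
  wsum <- as.numeric(wavelengths_nm)  # running sum of supporting wavelengths
  wcnt <- rep(1, n)                   # count of original (non-pad) positions
  pad <- 0L
  approximations <- details <- vector("list", levels)
  names(approximations) <- paste0("L", seq_len(levels))
  names(details) <- paste0("H", seq_len(levels))
  for (j in seq_len(levels)) {
    m <- length(cur)
    if (m %% 2L == 1L) {
      cur <- c(cur, cur[m])
      wsum <- c(wsum, 0)
      wcnt <- c(wcnt, 0)
      pad <- pad + 1L
      m <- m + 1L
    }
    i1 <- seq(1L, m, by = 2L)
    i2 <- i1 + 1L
    a <- (cur[i1] + cur[i2]) / sqrt(2)
    d <- (cur[i1] - cur[i2]) / sqrt(2)
    wsum <- wsum[i1] + wsum[i2]
    wcnt <- wcnt[i1] + wcnt[i2]
    axis <- wsum / wcnt
    approximations[[j]] <- list(values = a, axis_nm = axis)
    details[[j]] <- list(values = d, axis_nm = axis)
    cur <- a
  }
  structure(list(approximations = approximations, details = details,
                 levels = levels, pad_length = pad, input_ss = sum(x^2)),
            class = "haar_decomposition")
}

#' @export
print.haar_decomposition <- function(x, ...) {
  lens <- vapply(x$approximations, function(a) length(a$values), integer(1))
  cat(sprintf("<haar_decomposition> %d levels, lengths %s, %d pad value(s)\n",
              x$levels, paste(lens, collapse = "/"), x$pad_length))
  invisible(x)
}

#' Haar decomposition of every sample in a spectra set
#'
#' All samples share the grid, so coefficient axes are identical across
#' samples; each level/branch becomes a coefficient-by-sample matrix.
#'
#' @param dataset A [spectra_set()].
#' @param levels Decomposition depth.
#' @return Named list with one entry per tag (`L1`...`H<levels>`), each a
#'   list of `values` (matrix) and `axis_nm`.
#' @export
haar_dwt_set <- function(dataset, levels = 3L) {
  stopifnot(inherits(dataset, "spectra_set"))
  wl <- dataset$wavelength_nm
  decs <- lapply(seq_len(ncol(dataset$reflectance)), function(i) {
    haar_dwt(dataset$reflectance[, i], wl, levels)
  })
  out <- list()
  for (j in seq_len(levels)) {
    for (branch in c("approximations", "details")) {
      tag <- paste0(if (branch == "approximations") "L" else "H", j)
      vals <- vapply(decs, function(d) d[[branch]][[j]]$values,
                     numeric(length(decs[[1]][[branch]][[j]]$values)))
      vals <- matrix(vals, ncol = length(decs))
      colnames(vals) <- colnames(dataset$reflectance)
      out[[tag]] <- list(values = vals,
                         axis_nm = decs[[1]][[branch]][[j]]$axis_nm)
    }
  }
  out
}

#' Build the value matrix for one transform tag
#'
#' Dispatches a tag from [transform_tags()] to the corresponding
#' representation of a (smoothed, windowed) spectra set.
#'
#' @param dataset A [spectra_set()].
#' @param tag One of [transform_tags()].
#' @param clip_floor Passed to [inverse_reflectance()] / [log_reflectance()].
#' @param dwt Optional precomputed [haar_dwt_set()] result, to avoid
#'   redecomposing when several wavelet tags are requested.
#' @return List with `tag`, `axis_nm` and a bands-by-samples `values`
#'   matrix.
#' @export
build_representation <- function(dataset, tag, clip_floor = 1e-4, dwt = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (!tag %in% transform_tags()) {
    stop("unknown transform tag '", tag, "'", call. = FALSE)
  }
  wl <- dataset$wavelength_nm
  R <- dataset$reflectance
  strip <- function(v) { attributes(v) <- attributes(v)["dim"]; v }
  if (tag %in% c("L1", "L2", "L3", "H1", "H2", "H3")) {
    if (is.null(dwt)) dwt <- haar_dwt_set(dataset)
    rep <- dwt[[tag]]
    return(list(tag = tag, axis_nm = rep$axis_nm, values = rep$values))
  }
  base <- switch(tag,
    R = , dR = R,
    invR = , d_invR = strip(inverse_reflectance(R, clip_floor)),
    logR = , d_logR = strip(log_reflectance(R, clip_floor)))
  if (tag %in% c("dR", "d_invR", "d_logR")) {
    d <- first_derivative(base, wl)
    list(tag = tag, axis_nm = d$axis_nm, values = d$values)
  } else {
    list(tag = tag, axis_nm = wl, values = base)
  }
}
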