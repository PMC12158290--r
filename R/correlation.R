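# Band screening: per-band Pearson correlation against SPAD and greedy
# separation-constrained selection of sensitive bands.

#' Correlate every band of a representation with SPAD
#'
#' @param values Bands-by-samples matrix of transformed spectral values.
#' @param spad SPAD value per sample (length `ncol(values)`).
#' @param axis_nm Wavelength per band (length `nrow(values)`).
#' @param transform_tag Tag recorded on the profile.
#' @return A `correlation_profile` tibble with columns `wavelength_nm`,
#'   `r`, `r2` and attributes `transform_tag`, `n` (sample count) and
#'   `flagged_zero_variance` (indices of constant bands, which get
#'   `r = 0`).
#' @export
correlate <- function(values, spad, axis_nm, transform_tag = "R") {
  values <- as.matrix(values)
  if (ncol(values) != length(spad)) {
    stop(sprintf("%d spectra but %d SPAD values", ncol(values), length(spad)),
         call. = FALSE)
  }
  if (length(spad) < 3) stop("need at least 3 samples", call. = FALSE)
  if (nrow(values) != length(axis_nm)) {
    stop("axis_nm must have one entry per band", call. = FALSE)
  }
  if (stats::sd(spad) == 0) stop("SPAD values are constant", call. = FALSE)
  r <- suppressWarnings(drop(stats::cor(t(values), spad)))
  flagged <- which(is.na(r))
  r[flagged] <- 0
  out <- tibble::tibble(wavelength_nm = as.numeric(axis_nm),
                        r = as.numeric(r), r2 = as.numeric(r)^2)
  attr(out, "transform_tag") <- transform_tag
  attr(out, "n") <- length(spad)
  attr(out, "flagged_zero_variance") <- flagged
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Greedy selection of sensitive bands from a correlation profile
#'
#' Repeatedly takes the band with the largest `|r|` among those at least
#' `min_separation_nm` away from every band already selected, until `k`
#' bands are found or no feasible band remains. Ties in `|r|` go to the
#' shorter wavelength.
#'
#' @param profile A [correlate()] result.
#' @param k Number of bands wanted.
#' @param min_separation_nm Minimum pairwise distance between selected
#'   bands, in nm.
#' @return A `sensitive_bands` list: `transform_tag`, `bands_nm` (in
#'   selection order), `scores` (`|r|`, non-increasing), `min_separation_nm`
#'   and `complete` (`FALSE`, with a warning, when fewer than `k` feasible
#'   bands exist).
#' @export
select_bands <- function(profile, k = 2L, min_separation_nm = 50) {
  stopifnot(inherits(profile, "correlation_profile"), k >= 1)
  if (all(profile$r == 0)) {
    stop("degenerate profile: every band has zero correlation", call. = FALSE)
  }
  wl <- profile$wavelength_nm
  score <- abs(profile$r)
  ord <- order(-score, wl)
  sel <- integer(0)
  for (i in ord) {
    if (length(sel) == k) break
    if (all(abs(wl[i] - wl[sel]) >= min_separation_nm)) sel <- c(sel, i)
  }
  complete <- length(sel) == k
  if (!complete) {
    warning(sprintf("only %d of %d bands satisfiable at %g nm separation",
                    length(sel), k, min_separation_nm), call. = FALSE)
  }
  structure(list(transform_tag = attr(profile, "transform_tag"),
                 bands_nm = wl[sel],
                 scores = score[sel],
                 min_separation_nm = min_separation_nm,
                 complete = complete),
            class = "sensitive_bands")
}

#' @export
print.sensitive_bands <- function(x, ...) {
  cat(sprintf("<sensitive_bands> %s: %s (|r| = %s)\n", x$transform_tag,
              paste(round(x$bands_nm, 1), collapse = ", "),
              paste(round(x$scores, 3), collapse = ", ")))
  invisible(x)
}
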