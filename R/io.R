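# Wide-CSV spectra I/O and median-filter smoothing.

#' Median-filter smoothing parameters
#'
#' @param window_bands Odd positive window width in bands.
#' @param edge_mode `"reflect"` mirrors the series at each end (without
#'   duplicating the edge band); `"truncate"` shrinks the window near the
#'   edges.
#' @return A `smoothing_params` list.
#' @export
smoothing_params <- function(window_bands = 5L,
                             edge_mode = c("reflect", "truncate")) {
  edge_mode <- match.arg(edge_mode)
  window_bands <- as.integer(window_bands)
  if (window_bands < 1L || window_bands %% 2L == 0L) {
    stop("window_bands must be an odd positive integer", call. = FALSE)
  }
  structure(list(window_bands = window_bands, edge_mode = edge_mode),
            class = "smoothing_params")
}

running_median <- function(x, k, edge_mode) {
  if (k == 1L) return(x)
  n <- length(x)
  h <- (k - 1L) %/% 2L
  if (edge_mode == "reflect") {
    xp <- c(x[(h + 1L):2L], x, x[(n - 1L):(n - h)])
    r <- stats::runmed(xp, k, endrule = "keep")
    r[(h + 1L):(h + n)]
  } else {
    vapply(seq_len(n), function(i) {
      stats::median(x[max(1L, i - h):min(n, i + h)])
    }, numeric(1))
  }
}

#' Smooth every spectrum with a running median
#'
#' Removes isolated high-frequency spikes (dust) while preserving broad
#' absorption features and the red edge. SPAD labels and sample metadata
#' are unchanged.
#'
#' @param dataset A [spectra_set()].
#' @param params A [smoothing_params()].
#' @return The smoothed `spectra_set`.
#' @export
smooth_spectra <- function(dataset, params = smoothing_params()) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (!inherits(params, "smoothing_params")) {
    stop("`params` must come from smoothing_params()", call. = FALSE)
  }
  k <- params$window_bands
  if (k > length(dataset$wavelength_nm)) {
    stop("smoothing window wider than the wavelength grid", call. = FALSE)
  }
  sm <- apply(dataset$reflectance, 2L, running_median, k = k,
              edge_mode = params$edge_mode)
  dimnames(sm) <- dimnames(dataset$reflectance)
  dataset$reflectance <- sm
  dataset
}

#' Write a spectra set to wide CSV
#'
#' The spectra file is a pure numeric matrix: first column
#' `wavelength_nm`, then one column per sample id. Sample metadata
#' (direction, SPAD) goes to a companion labels CSV.
#'
#' @param dataset A non-empty [spectra_set()].
#' @param path Output path for the spectra CSV.
#' @param labels_path Output path for the labels CSV; default replaces the
#'   extension of `path` with `_labels.csv`.
#' @return Invisibly, `c(path, labels_path)`.
#' @export
write_spectra <- function(dataset, path, labels_path = NULL) {
  stopifnot(inherits(dataset, "spectra_set"))
  if (ncol(dataset$reflectance) == 0L) {
    stop("refusing to write an empty spectra set", call. = FALSE)
  }
  if (is.null(labels_path)) {
    labels_path <- sub("\\.[^.]*$", "", path)
    labels_path <- paste0(labels_path, "_labels.csv")
  }
  df <- data.frame(wavelength_nm = dataset$wavelength_nm,
                   dataset$reflectance, check.names = FALSE)
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    utils::write.csv(dataset$samples, labels_path, row.names = FALSE,
                     quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("could not write spectra: ", conditionMessage(ok),
                        call. = FALSE)
  invisible(c(path, labels_path))
}

#' Read a spectra set from wide CSV
#'
#' @param path Spectra CSV as written by [write_spectra()].
#' @param spad_path Optional labels CSV (`sample_id`, optional `direction`,
#'   `spad`); every spectra column must have a label row, and unmatched ids
#'   are reported.
#' @return A [spectra_set()]; SPAD is `NA` when no labels file is given.
#' @export
read_spectra <- function(path, spad_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (names(df)[1] != "wavelength_nm") {
    stop("first column must be 'wavelength_nm', found '", names(df)[1], "'",
         call. = FALSE)
  }
  non_num <- names(df)[!vapply(df, is.numeric, logical(1))]
  if (length(non_num)) {
    rows <- which(!vapply(df[[non_num[1]]], function(v)
      !is.na(suppressWarnings(as.numeric(v))), logical(1)))
    stop(sprintf("non-numeric cell(s) in column '%s' (row %s)", non_num[1],
                 paste(utils::head(rows, 5), collapse = ", ")), call. = FALSE)
  }
  wl <- df[[1]]
  d <- diff(wl)
  if (any(d <= 0)) {
    stop("wavelength column not strictly increasing at row(s): ",
         paste(utils::head(which(d <= 0) + 1L, 5), collapse = ", "),
         call. = FALSE)
  }
  if (diff(range(d)) > 1e-9) {
    bad <- which(abs(d - stats::median(d)) > 1e-9) + 1L
    stop("non-uniform wavelength spacing at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ids <- names(df)[-1]
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id column(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  samples <- tibble::tibble(sample_id = ids,
                            direction = NA_character_,
                            spad = NA_real_)
  if (!is.null(spad_path)) {
    lab <- utils::read.csv(spad_path)
    if (!all(c("sample_id", "spad") %in% names(lab))) {
      stop("labels file needs columns sample_id and spad", call. = FALSE)
    }
    missing <- setdiff(ids, lab$sample_id)
    if (length(missing)) {
      stop("no SPAD label for sample_id(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(lab$sample_id, ids)
    if (length(extra)) {
      warning("labels for unknown sample_id(s) ignored: ",
              paste(extra, collapse = ", "), call. = FALSE)
    }
    m <- match(ids, lab$sample_id)
    samples$spad <- lab$spad[m]
    if ("direction" %in% names(lab)) samples$direction <- lab$direction[m]
  }
  spectra_set(wavelength_nm = wl,
              reflectance = as.matrix(df[, -1, drop = FALSE]),
              samples = samples)
}

#' Restrict a spectra set to a wavelength window
#'
#' @param dataset A [spectra_set()].
#' @param window_nm Length-2 numeric `c(min, max)` in nm.
#' @return The windowed `spectra_set`.
#' @export
window_dataset <- function(dataset, window_nm) {
  stopifnot(inherits(dataset, "spectra_set"), length(window_nm) == 2)
  keep <- dataset$wavelength_nm >= window_nm[1] &
    dataset$wavelength_nm <= window_nm[2]
  if (sum(keep) < 8) stop("window leaves fewer than 8 bands", call. = FALSE)
  dataset$wavelength_nm <- dataset$wavelength_nm[keep]
  dataset$reflectance <- dataset$reflectance[keep, , drop = FALSE]
  dataset
}
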