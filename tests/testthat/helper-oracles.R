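# Independent oracles and small fixture builders used across the suite.

# Closed-form Haar coefficients at level j (block sums/half-differences,
# orthonormal scaling); independent of the cascade implementation.
oracle_haar_level <- function(x, j) {
  bs <- 2^j
  nb <- length(x) %/% bs
  a <- vapply(seq_len(nb), function(i) {
    sum(x[((i - 1) * bs + 1):(i * bs)])
  }, numeric(1)) / 2^(j / 2)
  d <- vapply(seq_len(nb), function(i) {
    blk <- x[((i - 1) * bs + 1):(i * bs)]
    (sum(blk[1:(bs / 2)]) - sum(blk[(bs / 2 + 1):bs]))
  }, numeric(1)) / 2^(j / 2)
  list(a = a, d = d)
}

# Inverse Haar cascade (synthesis), used only as a reconstruction oracle.
oracle_haar_inverse <- function(dec) {
  cur <- dec$approximations[[dec$levels]]$values
  for (j in rev(seq_len(dec$levels))) {
    d <- dec$details[[j]]$values
    x <- numeric(2 * length(cur))
    x[seq(1, length(x), by = 2)] <- (cur + d) / sqrt(2)
    x[seq(2, length(x), by = 2)] <- (cur - d) / sqrt(2)
    cur <- x
  }
  cur
}

# Brute-force separation-constrained band selection maximizing the
# lexicographically sorted |r| vector (ties toward shorter wavelengths).
oracle_select_bands <- function(wavelength_nm, r, k, min_sep) {
  subs <- utils::combn(seq_along(wavelength_nm), k, simplify = FALSE)
  feasible <- Filter(function(s) {
    all(stats::dist(wavelength_nm[s]) >= min_sep)
  }, subs)
  stopifnot(length(feasible) > 0)
  keys <- lapply(feasible, function(s) {
    o <- order(-abs(r[s]), wavelength_nm[s])
    rbind(abs(r[s])[o], -wavelength_nm[s][o])
  })
  best <- 1
  for (i in seq_along(keys)[-1]) {
    a <- keys[[i]]; b <- keys[[best]]
    cmp <- c(rbind(a[1, ] - b[1, ], a[2, ] - b[2, ]))
    nz <- which(abs(cmp) > 1e-15)
    if (length(nz) && cmp[nz[1]] > 0) best <- i
  }
  s <- feasible[[best]]
  sort(wavelength_nm[s])
}

# Two-pass textbook metric formulas.
oracle_r_squared <- function(m, p) {
  1 - sum((m - p)^2) / sum((m - mean(m))^2)
}
oracle_rmse <- function(m, p) sqrt(sum((m - p)^2) / length(m))

# Run a short python program (pre-installed interpreter) and return its
# exit status; args are appended to the script path.
run_python <- function(code, args = character()) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  system2("python", c(script, args), stdout = TRUE, stderr = TRUE)
}

# Tiny labelled spectra set on an 8-band grid, built in code.
tiny_spectra_set <- function(n = 3L, nbands = 8L) {
  wl <- seq(400, by = 1, length.out = nbands)
  set.seed(99)
  refl <- matrix(runif(nbands * n, 0.1, 0.5), nbands, n)
  ids <- sprintf("T%02d", seq_len(n))
  colnames(refl) <- ids
  spectra_set(wl, refl,
              tibble::tibble(sample_id = ids,
                             direction = rep("east", n),
                             spad = seq(40, by = 2, length.out = n)))
}

# Generator configs for common study conditions.
zero_noise_config <- function(seed = 1L, ...) {
  synthetic_config(smooth_noise_sd = 0, dust_noise_sd = 0,
                   spad_meter_error_sd = 0, seed = seed, ...)
}
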