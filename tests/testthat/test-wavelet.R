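test_that("Haar cascade reproduces hand-computed coefficients and axes", {
  dec <- haar_dwt(rep(1, 8), 1:8)
  expect_equal(dec$approximations$L1$values, rep(sqrt(2), 4))
  expect_equal(dec$approximations$L2$values, rep(2, 2))
  expect_equal(dec$approximations$L3$values, 2 * sqrt(2))
  for (j in 1:3) expect_equal(dec$details[[j]]$values,
                              rep(0, 2^(3 - j)))
  # coefficient -> wavelength mapping is the support midpoint
  expect_equal(dec$approximations$L1$axis_nm, c(1.5, 3.5, 5.5, 7.5))
  expect_equal(dec$approximations$L3$axis_nm, 4.5)
  expect_equal(dec$pad_length, 0L)

  two <- haar_dwt(c(1, 3, 5, 7), 1:4, levels = 2)
  expect_equal(two$approximations$L1$values, c(2 * sqrt(2), 6 * sqrt(2)))
  expect_equal(two$details$H1$values, c(-sqrt(2), -sqrt(2)))
  # Parseval by hand: 84 = (8 + 72) + (2 + 2)
  expect_equal(sum(c(1, 3, 5, 7)^2),
               sum(two$approximations$L1$values^2) +
                 sum(two$details$H1$values^2))
})

test_that("each level halves the resolution (ceiling division, reflect padding)", {
  for (n in c(8L, 13L, 21L, 100L, 676L)) {
    x <- sin(seq_len(n) / 3)
    dec <- haar_dwt(x, seq_len(n))
    lens <- unname(c(n, vapply(dec$approximations,
                               function(a) length(a$values), integer(1))))
    for (j in 1:3) expect_equal(lens[j + 1], ceiling(lens[j] / 2))
    expect_equal(unname(vapply(dec$details, function(d) length(d$values),
                               integer(1))),
                 lens[-1])
  }
  expect_error(haar_dwt(1:7, 1:7), "too short")
})

test_that("coefficients match the closed-form block-sum oracle", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(64)
    dec <- haar_dwt(x, seq_len(64))
    for (j in 1:3) {
      ref <- oracle_haar_level(x, j)
      expect_equal(dec$approximations[[j]]$values, ref$a, tolerance = 1e-12)
      expect_equal(dec$details[[j]]$values, ref$d, tolerance = 1e-12)
    }
  }
})

test_that("the transform conserves energy and is perfectly invertible", {
  set.seed(22)
  for (rep in 1:10) {
    x <- rnorm(128)
    dec <- haar_dwt(x, seq_len(128))
    energy <- sum(dec$approximations$L3$values^2) +
      sum(vapply(dec$details, function(d) sum(d$values^2), numeric(1)))
    expect_equal(energy, sum(x^2), tolerance = 1e-9)
    expect_equal(oracle_haar_inverse(dec), x, tolerance = 1e-10)
  }
})

test_that("alternating-sign noise lands in H1, leaving L3 nearly untouched", {
  wl <- seq_len(256)
  x <- 0.3 + 0.1 * sin(wl / 40)
  set.seed(33)
  # +e, -e within each sample pair: pure detail-space perturbation
  noise <- rep(0.02 * abs(rnorm(128)), each = 2) * rep(c(1, -1), 128)
  clean <- haar_dwt(x, wl)
  noisy <- haar_dwt(x + noise, wl)
  dh1 <- sum((noisy$details$H1$values - clean$details$H1$values)^2)
  dl3 <- sum((noisy$approximations$L3$values -
                clean$approximations$L3$values)^2)
  expect_equal(dh1, sum(noise^2), tolerance = 1e-10)  # all of it lands in H1
  expect_equal(dl3, 0, tolerance = 1e-20)
})

test_that("haar_dwt_set stacks per-sample decompositions on one shared axis", {
  ds <- tiny_spectra_set(n = 4, nbands = 16)
  tags <- haar_dwt_set(ds)
  expect_setequal(names(tags), c("L1", "L2", "L3", "H1", "H2", "H3"))
  expect_equal(dim(tags$L1$values), c(8L, 4L))
  ref <- haar_dwt(ds$reflectance[, 3], ds$wavelength_nm)
  expect_equal(unname(tags$H2$values[, 3]), ref$details$H2$values)
  expect_equal(tags$L3$axis_nm, ref$approximations$L3$axis_nm)
})
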