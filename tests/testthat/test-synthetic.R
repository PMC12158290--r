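test_that("generated dataset matches the campaign design and is reproducible", {
  cfg <- synthetic_config(seed = 7L)
  ds <- generate_dataset(cfg)
  expect_equal(n_samples(ds), 87L)
  expect_equal(as.vector(table(ds$samples$direction)[c("east", "south",
                                                       "west", "north")]),
               c(22L, 22L, 22L, 21L))
  expect_true(all(ds$samples$spad >= cfg$spad_min &
                    ds$samples$spad <= cfg$spad_max))
  expect_true(all(ds$reflectance >= 0 & ds$reflectance <= 1))
  expect_false(anyNA(ds$reflectance))
  # same seed + config -> bit-identical dataset
  expect_identical(ds, generate_dataset(cfg))
  # different seed -> different draws
  expect_false(identical(ds$reflectance,
                         generate_dataset(synthetic_config(seed = 8L))$reflectance))
})

test_that("SPAD sample moments approach the configured mean and SD", {
  cfg <- synthetic_config(
    n_samples = 10000L,
    direction_counts = c(east = 2500L, south = 2500L, west = 2500L,
                         north = 2500L),
    spad_meter_error_sd = 0, seed = 11L)
  ds <- generate_dataset(cfg)
  expect_lt(abs(mean(ds$samples$spad) - 45.8) / 45.8, 0.02)
  expect_lt(abs(sd(ds$samples$spad) - 3.64) / 3.64, 0.02)
})

test_that("with zero noise, reflectance at a planted well center decreases in SPAD", {
  ds <- generate_dataset(zero_noise_config(seed = 3L))
  for (center in c(450, 670)) {
    at <- ds$reflectance[match(center, ds$wavelength_nm), ]
    o <- order(ds$truth$spad_true)
    expect_true(all(diff(at[o]) < 0))
  }
})

test_that("zero noise and equal SPAD give identical reflectance vectors", {
  cfg <- zero_noise_config(seed = 5L, n_samples = 2L,
                           direction_counts = c(east = 1L, south = 1L,
                                                west = 0L, north = 0L),
                           spad_sd = 0,
                           feature_bands = data.frame(center_nm = 670,
                                                      width_nm = 30,
                                                      sensitivity = 0.0012))
  ds <- generate_dataset(cfg)
  expect_identical(ds$reflectance[, 1], unname(ds$reflectance[, 2]))
})

test_that("dust noise raises high-frequency content; smooth components obey a slope bound", {
  quiet <- generate_dataset(synthetic_config(seed = 13L, dust_noise_sd = 0))
  dusty <- generate_dataset(synthetic_config(seed = 13L, dust_noise_sd = 0.01))
  mad1 <- mean(abs(diff(quiet$reflectance[, 1])))
  mad2 <- mean(abs(diff(dusty$reflectance[, 1])))
  expect_gt(mad2, mad1)
  # per-nm slope of logistic edge + wells + low-order drift is small
  expect_lt(max(abs(diff(quiet$reflectance))), 0.01)
})

test_that("invalid configurations are rejected with informative errors", {
  expect_error(synthetic_config(n_samples = 80L), "direction_counts")
  expect_error(synthetic_config(spad_mean = 30), "spad_min < spad_mean")
  expect_error(synthetic_config(dust_noise_sd = -1), "must be >= 0")
  expect_error(synthetic_config(feature_bands = data.frame(
    center_nm = 3000, width_nm = 30, sensitivity = 0.001)),
    "outside the wavelength grid")
  expect_error(synthetic_config(wavelength_nm = 400:405), "at least 8 bands")
  expect_error(synthetic_config(wavelength_nm = c(400:410, 420)), "uniform")
})
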