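test_that("read_spectra validates, aligns and reports mismatches", {
  dir <- withr::local_tempdir()
  paths <- write_toy_csvs(dir)
  got <- read_spectra(paths["spectra"], paths["lnc"])
  expect_s3_class(got$spectra, "spectrum_set")
  expect_equal(dim(got$spectra$reflectance), c(3, 501))
  expect_equal(got$lnc$sample_id, got$spectra$sample_ids)

  # LNC file missing one sample -> aligned 2 samples, drop reported
  paths2 <- write_toy_csvs(dir, ids = c("a", "b", "c"), lnc_ids = c("a", "b"))
  expect_message(got2 <- read_spectra(paths2["spectra"], paths2["lnc"]),
                 "only one file")
  expect_equal(n_samples(got2$spectra), 2)

  # descending wavelengths -> hard error
  bad <- file.path(dir, "desc.csv")
  utils::write.csv(data.frame(wavelength = c(500, 499, 498), a = c(.1, .2, .3)),
                   bad, row.names = FALSE)
  expect_error(read_spectra(bad, paths["lnc"]), "strictly increasing")

  expect_error(read_spectra(file.path(dir, "nope.csv"), paths["lnc"]),
               "not found")
})

test_that("percent-scale reflectance is detected and rescaled", {
  dir <- withr::local_tempdir()
  wl <- 400:500
  utils::write.csv(data.frame(wavelength = wl, a = rep(25, 101)),
                   file.path(dir, "pct.csv"), row.names = FALSE)
  utils::write.csv(data.frame(sample_id = "a", lnc = 1.5),
                   file.path(dir, "lnc.csv"), row.names = FALSE)
  expect_message(got <- read_spectra(file.path(dir, "pct.csv"),
                                     file.path(dir, "lnc.csv")),
                 "percent")
  expect_equal(unique(as.vector(got$spectra$reflectance)), 0.25)
})

test_that("spectra are resampled onto a 1 nm grid at read time", {
  wl <- seq(400, 900, by = 1.4)
  s <- fun_set(function(l) 0.1 + 0.0004 * l, wl)
  rs <- resample_grid(s)
  expect_equal(rs$wavelengths, 400:899)
  # linear spectra are reproduced exactly by linear interpolation
  expect_equal(as.vector(rs$reflectance), 0.1 + 0.0004 * (400:899),
               tolerance = 1e-12)
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials", {
  wl <- 400:900
  const <- fun_set(function(l) rep(0.3, length(l)), wl)
  expect_equal(sg_smooth(const)$reflectance, const$reflectance,
               tolerance = 1e-10)

  # exactness on a quadratic holds at every point, including the edges,
  # because truncated windows still fit the quadratic exactly
  quad <- fun_set(function(l) 0.2 + 1e-4 * l + 2e-7 * l^2, wl)
  sm <- sg_smooth(quad, window = 17, polyorder = 2)
  expect_equal(sm$reflectance, quad$reflectance, tolerance = 1e-10)

  expect_equal(eval(formals(sg_smooth)$window), 17)
  expect_equal(eval(formals(sg_smooth)$polyorder), 2)
  expect_error(sg_smooth(const, window = 16), "odd")
  expect_error(sg_smooth(const, window = 1001), "shorter")
})

test_that("first derivative is the midpoint finite difference in nm^-1", {
  s <- spectrum_set(c(700, 701), matrix(c(0.2, 0.3), 1), "S1")
  fd <- first_derivative(s)
  expect_equal(fd$wavelengths, 700.5)
  expect_equal(as.vector(fd$reflectance), 0.1)

  lin <- fun_set(function(l) 0.05 + 3e-4 * l, 500:600)
  fdl <- first_derivative(lin)
  expect_equal(as.vector(fdl$reflectance), rep(3e-4, 100), tolerance = 1e-12)
  expect_length(fdl$wavelengths, 100)

  const <- fun_set(function(l) rep(0.4, length(l)), 500:600)
  expect_true(all(first_derivative(const)$reflectance == 0))

  expect_error(first_derivative(spectrum_set(700, matrix(0.2, 1), "S1")),
               "at least 2")
})

test_that("cumulative trapezoid of the derivative rebuilds a linear spectrum", {
  lin <- fun_set(function(l) 0.1 + 2e-4 * l, 500:600)
  fd <- first_derivative(lin)
  mid <- fd$wavelengths
  rise <- c(pracma::cumtrapz(mid, as.vector(fd$reflectance)))
  # integrating the derivative recovers the linear rise exactly
  expect_equal(rise, 2e-4 * (mid - mid[1]), tolerance = 1e-12)
})

test_that("water-vapor masking keeps exactly the configured windows", {
  s <- fun_set(function(l) rep(0.5, length(l)), 350:2500)
  masked <- apply_mask(s)
  expect_equal(length(masked$wavelengths), 954 + 363 + 363)
  # retained set equals brute-force membership, order preserved
  keep <- (350:2500 >= 400 & 350:2500 <= 1353) |
    (350:2500 >= 1437 & 350:2500 <= 1799) |
    (350:2500 >= 1992 & 350:2500 <= 2354)
  expect_equal(masked$wavelengths, as.numeric((350:2500)[keep]))
  expect_false(is.unsorted(masked$wavelengths))

  one <- apply_mask(s, wavelength_mask(list(c(400, 400))))
  expect_equal(one$wavelengths, 400)

  expect_error(apply_mask(s, wavelength_mask(list(c(3000, 3100)))),
               "every wavelength")
  expect_error(wavelength_mask(list(c(400, 500), c(450, 600))), "disjoint")
})

test_that("spectrum_set enforces its invariants", {
  expect_error(spectrum_set(c(500, 500, 501), matrix(0.1, 1, 3)),
               "strictly increasing")
  expect_error(spectrum_set(500:502, matrix(c(0.1, NA, 0.2), 1)), "finite")
  expect_error(spectrum_set(500:502, matrix(0.1, 2, 3), c("a", "a")),
               "duplicate")
  expect_error(spectrum_set(500:502, matrix(0.1, 1, 2)), "equal length")
})
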