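test_that("continuum line is the endpoint chord", {
  flat <- fun_set(function(l) rep(0.4, length(l)), 500:800)
  rg <- spectral_region("A1", "absorption", 560, 760)
  cl <- continuum_line(flat, rg)
  expect_true(all(cl$chord == 0.4))

  ramp <- anchor_set(cbind(c(560, 760), c(0.2, 0.4)), 500:800)
  cl2 <- continuum_line(ramp, rg)
  expect_equal(cl2$chord[cl2$wavelengths == 660], 0.3)
  expect_equal(cl2$chord[1], cl2$reflectance[1])
  expect_equal(cl2$chord[length(cl2$chord)],
               cl2$reflectance[length(cl2$reflectance)])

  expect_error(continuum_line(flat, spectral_region("X", "absorption",
                                                    1000, 1200)),
               "< 3 points")
})

test_that("absorption features match hand-derived triangle values", {
  dip <- vee_set(0.5, 0.3)
  rg <- spectral_region("A1", "absorption", 0, 10)
  f <- absorption_features(dip, rg)
  expect_equal(unname(f["depth"]), 1 - 0.3 / 0.5)
  expect_equal(unname(f["area"]), 1.0) # triangle: 0.5 * base 10 * height 0.2
  expect_equal(unname(f["nd"]), 0.4 / 1.0)

  flat <- spectrum_set(0:10, matrix(0.5, 1, 11), "S1")
  expect_equal(unname(absorption_features(flat, rg)), c(0, 0, 0))
})

test_that("reflection features mirror the absorption definitions", {
  peak <- vee_set(0.3, 0.5)
  rg <- spectral_region("R1", "reflection", 0, 10)
  f <- reflection_features(peak, rg)
  expect_equal(unname(f["depth"]), 1 - 0.3 / 0.5)
  expect_equal(unname(f["area"]), 1.0)
  expect_equal(unname(f["nd"]), 0.4)

  flat <- spectrum_set(0:10, matrix(0.5, 1, 11), "S1")
  expect_equal(unname(reflection_features(flat, rg)), c(0, 0, 0))

  # apex below the chord: depth <= 0, reported as degenerate
  sag <- vee_set(0.5, 0.3)
  expect_message(fs <- reflection_features(sag, rg), "degenerate")
  expect_lte(unname(fs["depth"]), 0)

  expect_error(reflection_features(peak,
                                   spectral_region("A", "absorption", 0, 10)),
               "not a reflection")
})

test_that("scaling the spectrum leaves depth unchanged and scales area", {
  set.seed(3)
  s <- fun_set(function(l) 0.5 - 0.2 * exp(-(l - 660)^2 / 800), 500:800)
  rg <- spectral_region("A1", "absorption", 560, 760)
  f1 <- absorption_features(s, rg)
  s3 <- spectrum_set(s$wavelengths, 3 * s$reflectance, s$sample_ids)
  f3 <- absorption_features(s3, rg)
  expect_equal(f3["depth"], f1["depth"], tolerance = 1e-12)
  expect_equal(unname(f3["area"]), unname(3 * f1["area"]), tolerance = 1e-12)
})

test_that("trapezoid areas agree with an oversampled Simpson oracle", {
  f <- function(l) 0.5 - 0.2 * exp(-(l - 660)^2 / 800)
  s <- fun_set(f, 500:800)
  rg <- spectral_region("A1", "absorption", 560, 760)
  area <- absorption_features(s, rg)[["area"]]
  chord <- function(l) f(560) + (f(760) - f(560)) * (l - 560) / 200
  oracle <- pracma::simpadpt(function(l) chord(l) - f(l), 560, 760, tol = 1e-10)
  expect_lt(abs(area - oracle) / oracle, 0.01)
})

test_that("edge parameters on a linear ramp reduce to the constant slope", {
  c0 <- 4e-4
  ramp <- fun_set(function(l) 0.05 + c0 * l, 400:800)
  fd <- first_derivative(ramp)
  ep <- edge_parameters(ramp, fd)
  expect_equal(unname(ep[c("Db", "Dy", "Dr")]), rep(c0, 3), tolerance = 1e-12)
  # constant integrand: integral = slope * covered span (midpoint grid spans
  # 39 of the 40 nm blue-edge window)
  span <- diff(range(fd$wavelengths[fd$wavelengths >= 490 &
                                      fd$wavelengths <= 530]))
  expect_equal(unname(ep["SDb"]), c0 * span, tolerance = 1e-12)
  expect_equal(unname(ep["SDb"]), c0 * 40, tolerance = 0.03)
  expect_equal(unname(ep["Rg"]), 0.05 + c0 * 560) # ramp max at window top
  expect_equal(unname(ep["lambda_o"]), 650) # ramp min at window bottom
})

test_that("a sigmoid red edge puts lambda_r at its inflection", {
  s <- fun_set(function(l) 0.05 + 0.45 * stats::plogis((l - 715) / 10), 400:900)
  ep <- edge_parameters(s, first_derivative(s))
  expect_lte(abs(ep[["lambda_r"]] - 715), 1)
})

test_that("argmax ties resolve to the smallest wavelength", {
  # two equal derivative maxima inside the blue edge
  fdv <- rep(0.001, 401)
  fdv[c(110, 120)] <- 0.01 # wavelengths 509 and 519 on a 400:800 grid
  fd <- spectrum_set(400:800, matrix(fdv, 1), "S1")
  raw <- fun_set(function(l) rep(0.3, length(l)), 400:800)
  ep <- edge_parameters(raw, fd)
  expect_equal(unname(ep["lambda_b"]), 509)
})

test_that("the position feature vector has 40 canonically ordered entries", {
  nms <- position_feature_names()
  expect_length(nms, 40)
  expect_identical(nms[1:3], c("A_Depth_1", "A_Area_1", "A_ND_1"))
  expect_identical(nms[10:12], c("R_Depth_1", "R_Area_1", "R_ND_1"))
  expect_identical(nms[28:40],
                   c("Db", "lambda_b", "Dy", "lambda_y", "Dr", "lambda_r",
                     "Rg", "lambda_g", "Ro", "lambda_o", "SDb", "SDy", "SDr"))

  cfg <- sim_config(seed = 11, n_samples = 3, noise_sd = 0.002)
  ds <- make_dataset(cfg)
  sm <- sg_smooth(ds$spectra)
  feats <- position_features(apply_mask(sm), apply_mask(first_derivative(sm)))
  expect_identical(colnames(feats), nms)
  expect_equal(nrow(feats), 3)

  # per-sample computation: adding samples never changes earlier rows
  one <- position_features(apply_mask(get_spectrum(sm, 1)),
                           apply_mask(first_derivative(get_spectrum(sm, 1))))
  expect_equal(feats[1, ], one[1, ])
})

test_that("edge wavelengths always fall inside their windows", {
  cfg <- sim_config(seed = 21, n_samples = 10, noise_sd = 0.01)
  ds <- make_dataset(cfg)
  sm <- sg_smooth(ds$spectra)
  feats <- position_features(apply_mask(sm), apply_mask(first_derivative(sm)))
  expect_true(all(feats[, "lambda_b"] >= 490 & feats[, "lambda_b"] <= 530))
  expect_true(all(feats[, "lambda_y"] >= 560 & feats[, "lambda_y"] <= 640))
  expect_true(all(feats[, "lambda_r"] >= 680 & feats[, "lambda_r"] <= 760))
  expect_true(all(feats[, "lambda_g"] >= 510 & feats[, "lambda_g"] <= 560))
  expect_true(all(feats[, "lambda_o"] >= 650 & feats[, "lambda_o"] <= 690))
})

test_that("the SDr window is configurable between red edge and red well", {
  cfg <- sim_config(seed = 5, n_samples = 1, noise_sd = 0)
  ds <- make_dataset(cfg)
  sm <- sg_smooth(ds$spectra)
  fd <- apply_mask(first_derivative(sm))
  raw <- apply_mask(sm)
  a <- edge_parameters(raw, fd, sdr_window = "red_edge")
  b <- edge_parameters(raw, fd, sdr_window = "red_well")
  expect_false(isTRUE(all.equal(a[["SDr"]], b[["SDr"]])))
  expect_equal(a[-13], b[-13]) # only SDr differs
})
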