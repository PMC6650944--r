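#' Configuration for synthetic corn-canopy spectra
#'
#' The generator is phenomenological (Gaussian pigments/water wells plus a
#' logistic red edge), not radiative transfer: it exists so every pipeline
#' stage can be exercised and its recovery properties measured without field
#' data. Nitrogen enters through three monotone links: chlorophyll
#' absorption wells near 490 and 670 nm deepen with LNC, the red-edge
#' inflection shifts to longer wavelengths, and the NIR plateau rises
#' mildly (a biomass proxy).
#'
#' @param n_samples Number of samples (default 72, split 48/24).
#' @param lnc_mean,lnc_sd Target moments of the truncated-normal LNC draw
#'   (% dry mass); defaults 1.91 and 0.59.
#' @param lnc_range Truncation interval, default `c(0.82, 2.83)`.
#' @param red_edge_gain Red-edge inflection shift, nm per unit LNC
#'   (default 8).
#' @param chl_gain Chlorophyll-well depth gain, reflectance units per unit
#'   LNC (default 0.035).
#' @param nir_gain NIR plateau gain, reflectance per unit LNC (default 0.02).
#' @param noise_sd Instrument noise standard deviation in reflectance units
#'   (default 0.005).
#' @param seed Mandatory RNG seed.
#' @param grid Wavelength grid in nm (default 350-2500 step 1).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_samples = 72, lnc_mean = 1.91, lnc_sd = 0.59,
                       lnc_range = c(0.82, 2.83), red_edge_gain = 8,
                       chl_gain = 0.035, nir_gain = 0.02, noise_sd = 0.005,
                       seed, grid = seq(350, 2500, by = 1)) {
  if (missing(seed)) stop("seed is mandatory")
  if (lnc_range[1] <= 0 || lnc_range[2] >= 5 || lnc_range[1] >= lnc_range[2])
    stop("lnc_range must lie within (0, 5)")
  if (lnc_mean <= lnc_range[1] || lnc_mean >= lnc_range[2])
    stop("lnc_mean outside lnc_range: infeasible")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(n_samples = as.integer(n_samples), lnc_mean = lnc_mean,
                 lnc_sd = lnc_sd, lnc_range = lnc_range,
                 red_edge_gain = red_edge_gain, chl_gain = chl_gain,
                 nir_gain = nir_gain, noise_sd = noise_sd,
                 seed = as.integer(seed), grid = grid),
            class = "sim_config")
}

#' Draw LNC values from a truncated normal
#'
#' Inverse-CDF sampling of a normal with the configured mean and sd,
#' truncated to `lnc_range`. With the default configuration the sample mean
#' lands within three standard errors of the target.
#'
#' @param cfg A `sim_config`.
#' @param n Number of draws (default `cfg$n_samples`).
#' @return Numeric LNC vector.
#' @export
simulate_lnc <- function(cfg, n = cfg$n_samples) {
  lo <- stats::pnorm(cfg$lnc_range[1], cfg$lnc_mean, cfg$lnc_sd)
  hi <- stats::pnorm(cfg$lnc_range[2], cfg$lnc_mean, cfg$lnc_sd)
  if (hi - lo < 1e-6) stop("lnc_range/moments combination is infeasible")
  stats::qnorm(stats::runif(n, lo, hi), cfg$lnc_mean, cfg$lnc_sd)
}

gauss <- function(x, center, width) exp(-(x - center)^2 / (2 * width^2))

#' Deterministic canopy reflectance curve for one LNC value
#'
#' Base curve: low visible reflectance with a Gaussian green peak near
#' 550 nm; chlorophyll wells at 490 and 670 nm deepening linearly with LNC;
#' logistic red edge with inflection at `700 + red_edge_gain * LNC` nm
#' rising to a NIR plateau `0.45 + nir_gain * LNC`; a gentle SWIR decline
#' with water-absorption wells near 1450 and 1940 nm. No noise.
#'
#' @param lnc LNC value (% dry mass).
#' @param cfg A `sim_config`.
#' @return Numeric reflectance vector on `cfg$grid`, clipped to [0, 1].
#' @export
canopy_curve <- function(lnc, cfg) {
  lam <- cfg$grid
  chl <- cfg$chl_gain * lnc
  vis <- 0.16 + 0.06 * gauss(lam, 550, 25) -
    chl * (0.8 * gauss(lam, 490, 18) + gauss(lam, 670, 28))
  plateau <- 0.45 + cfg$nir_gain * lnc
  re_center <- 700 + cfg$red_edge_gain * lnc
  s <- stats::plogis((lam - re_center) / 12)
  r <- vis * (1 - s) + plateau * s
  swir <- 1 - 0.30 * stats::plogis((lam - 1400) / 200) -
    0.45 * gauss(lam, 1450, 35) - 0.55 * gauss(lam, 1940, 45)
  pmin(pmax(r * pmax(swir, 0), 0), 1)
}

#' Simulate one canopy spectrum
#'
#' [canopy_curve()] plus i.i.d. Gaussian instrument noise of sd
#' `cfg$noise_sd`, clipped to [0, 1]. With `noise_sd = 0` the output is a
#' deterministic function of (`lnc`, `cfg`).
#'
#' @param lnc LNC value.
#' @param cfg A `sim_config`.
#' @return A one-sample `spectrum_set`.
#' @export
simulate_spectrum <- function(lnc, cfg) {
  r <- canopy_curve(lnc, cfg)
  if (cfg$noise_sd > 0) r <- r + stats::rnorm(length(r), 0, cfg$noise_sd)
  spectrum_set(cfg$grid, matrix(pmin(pmax(r, 0), 1), nrow = 1))
}

#' Generate a full synthetic dataset
#'
#' Draws LNC values, simulates one spectrum per sample, and records a random
#' 2:1 calibration:validation split (48/24 at the default n = 72). All
#' randomness flows from `cfg$seed`, so the dataset is reproducible
#' bit-for-bit.
#'
#' @param cfg A `sim_config`.
#' @return An object of class `synthetic_dataset`: list with `spectra`
#'   (a `spectrum_set`), `lnc` (data.frame `sample_id`, `lnc`), `split`
#'   (list `calibration`, `validation` of sample ids) and `config`.
#' @export
make_dataset <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_samples
  lnc <- simulate_lnc(cfg, n)
  ids <- sprintf("S%02d", seq_len(n))
  m <- t(vapply(lnc, function(v) {
    r <- canopy_curve(v, cfg)
    if (cfg$noise_sd > 0) r <- r + stats::rnorm(length(r), 0, cfg$noise_sd)
    pmin(pmax(r, 0), 1)
  }, numeric(length(cfg$grid))))
  n_cal <- round(2 / 3 * n)
  cal <- sort(sample.int(n, n_cal))
  structure(list(spectra = spectrum_set(cfg$grid, m, ids),
                 lnc = data.frame(sample_id = ids, lnc = lnc),
                 split = list(calibration = ids[cal],
                              validation = ids[-cal]),
                 config = cfg),
            class = "synthetic_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Emits the spectra/LNC CSV dialects the pipeline reads plus a manifest
#' JSON recording the configuration, seed and split.
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_spectra(ds$spectra, ds$lnc,
                file.path(dir, "spectra.csv"), file.path(dir, "lnc.csv"))
  cfg <- ds$config
  cfg$grid <- c(min(cfg$grid), max(cfg$grid), cfg$grid[2] - cfg$grid[1])
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(config = unclass(cfg), split = ds$split,
                            split_rule = "random 2:1 by seed"),
                       manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
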