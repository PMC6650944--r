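#' Spectral region definition
#'
#' A named absorption or reflection interval of the canopy spectrum over
#' which continuum-removal features are computed.
#'
#' @param name Label, e.g. `"A1"`.
#' @param kind `"absorption"` or `"reflection"`.
#' @param lo,hi Interval bounds in nm, `lo < hi`.
#' @param index Region number within its kind.
#' @return An object of class `spectral_region`.
#' @export
spectral_region <- function(name, kind = c("absorption", "reflection"), lo, hi,
                            index = 1L) {
  kind <- match.arg(kind)
  if (!(lo < hi)) stop("region needs lo < hi")
  structure(list(name = name, kind = kind, lo = lo, hi = hi,
                 index = as.integer(index)), class = "spectral_region")
}

#' Default absorption regions
#'
#' The three chlorophyll/water absorption troughs of the corn canopy
#' spectrum: 560-760, 920-1080 and 1120-1280 nm.
#' @return List of `spectral_region`.
#' @export
absorption_regions <- function() {
  b <- list(c(560, 760), c(920, 1080), c(1120, 1280))
  lapply(seq_along(b), function(i)
    spectral_region(paste0("A", i), "absorption", b[[i]][1], b[[i]][2], i))
}

#' Default reflection regions
#'
#' The six reflectance shoulders: 500-670, 780-970, 980-1200, 1200-1350,
#' 1480-1720 and 2000-2300 nm.
#' @return List of `spectral_region`.
#' @export
reflection_regions <- function() {
  b <- list(c(500, 670), c(780, 970), c(980, 1200),
            c(1200, 1350), c(1480, 1720), c(2000, 2300))
  lapply(seq_along(b), function(i)
    spectral_region(paste0("R", i), "reflection", b[[i]][1], b[[i]][2], i))
}

# Indices of the grid points inside a region, after intersection with the
# available (possibly masked) grid. A region losing more than 10% of its
# nominal span is reported.
region_index <- function(wl, region) {
  idx <- which(wl >= region$lo & wl <= region$hi)
  if (length(idx) >= 2) {
    got <- wl[idx[length(idx)]] - wl[idx[1]]
    if (got < 0.9 * (region$hi - region$lo))
      message("region ", region$name, " truncated to ", round(got),
              " nm of its ", region$hi - region$lo, " nm span")
  }
  idx
}

#' Continuum line over a region
#'
#' The straight chord joining the spectrum's values at the region endpoints,
#' evaluated on the in-region grid. Dividing reflectance by this chord
#' (continuum removal) isolates the shape of the absorption or reflection
#' feature.
#'
#' @param s A single-sample `spectrum_set` (or one row is taken with a
#'   warning).
#' @param region A `spectral_region`.
#' @return List with `wavelengths`, `reflectance`, `chord` on the region grid.
#' @export
continuum_line <- function(s, region) {
  stopifnot(inherits(s, "spectrum_set"))
  if (n_samples(s) != 1L) stop("continuum_line expects a single spectrum")
  idx <- region_index(s$wavelengths, region)
  if (length(idx) < 3) stop("region ", region$name, " overlaps the grid by < 3 points")
  wl <- s$wavelengths[idx]
  r <- s$reflectance[1L, idx]
  n <- length(wl)
  chord <- r[1] + (r[n] - r[1]) * (wl - wl[1]) / (wl[n] - wl[1])
  list(wavelengths = wl, reflectance = r, chord = chord)
}

#' Continuum-removal absorption features
#'
#' Depth, area and normalized depth of an absorption trough: with `Rc` the
#' continuum chord, `lambda_min` minimizes the continuum-removed ratio
#' `R/Rc`; depth = `1 - R(lambda_min)/Rc(lambda_min)`; area =
#' `integral(Rc - R) d lambda` (trapezoid, nm); normalized depth =
#' depth / area (nm^-1), defined as 0 when both depth and area vanish.
#'
#' @param s Single-sample `spectrum_set`.
#' @param region An absorption `spectral_region`.
#' @return Named numeric: `depth`, `area`, `nd`.
#' @export
absorption_features <- function(s, region) {
  if (region$kind != "absorption") stop("region is not an absorption region")
  cl <- continuum_line(s, region)
  ratio <- cl$reflectance / cl$chord
  i <- which.min(ratio) # which.min returns the first (smallest wavelength) tie
  if (cl$chord[i] <= 0) stop("continuum line non-positive at the trough")
  depth <- 1 - cl$reflectance[i] / cl$chord[i]
  area <- pracma::trapz(cl$wavelengths, cl$chord - cl$reflectance)
  nd <- if (area == 0 && depth == 0) 0 else depth / area
  c(depth = depth, area = area, nd = nd)
}

#' Continuum-removal reflection features
#'
#' Mirror of [absorption_features()] for reflectance shoulders:
#' `lambda_max` maximizes `R/Rc`; depth = `1 - Rc(lambda_max)/R(lambda_max)`;
#' area = `integral(R - Rc) d lambda`; normalized depth = depth / area.
#'
#' @param s Single-sample `spectrum_set`.
#' @param region A reflection `spectral_region`.
#' @return Named numeric: `depth`, `area`, `nd`.
#' @export
reflection_features <- function(s, region) {
  if (region$kind != "reflection") stop("region is not a reflection region")
  cl <- continuum_line(s, region)
  ratio <- cl$reflectance / cl$chord
  i <- which.max(ratio)
  if (cl$reflectance[i] <= 0) stop("reflectance non-positive at the peak")
  depth <- 1 - cl$chord[i] / cl$reflectance[i]
  if (depth <= 0 && any(cl$reflectance != cl$chord))
    message("region ", region$name, ": peak below the chord (degenerate shoulder)")
  area <- pracma::trapz(cl$wavelengths, cl$reflectance - cl$chord)
  nd <- if (area == 0 && depth == 0) 0 else depth / area
  c(depth = depth, area = area, nd = nd)
}

# window helper: values and wavelengths of a spectrum row inside [lo, hi]
window_slice <- function(s, lo, hi) {
  idx <- which(s$wavelengths >= lo & s$wavelengths <= hi)
  if (!length(idx)) stop("window [", lo, ", ", hi, "] nm is empty on this grid")
  list(wl = s$wavelengths[idx], v = s$reflectance[1L, idx])
}

#' Edge and peak parameters
#'
#' The thirteen classical red/blue/yellow-edge and green-peak/red-well
#' parameters: maxima of the first-derivative spectrum and their wavelengths
#' over the blue (490-530 nm), yellow (560-640 nm) and red (680-760 nm)
#' edges (`Db, lambda_b, Dy, lambda_y, Dr, lambda_r`); the green-peak
#' reflectance maximum and red-well reflectance minimum with their
#' wavelengths (`Rg, lambda_g` over 510-560 nm; `Ro, lambda_o` over
#' 650-690 nm); and the integrals of the first derivative over the three
#' edge windows (`SDb, SDy, SDr`). Argmax/argmin ties resolve to the
#' smallest wavelength.
#'
#' @param s_raw Single-sample `spectrum_set` of (smoothed, masked) reflectance.
#' @param s_fd Single-sample `spectrum_set` of first-derivative values on the
#'   midpoint grid.
#' @param sdr_window `"red_edge"` (default) integrates SDr over 680-760 nm,
#'   consistent with SDb/SDy; `"red_well"` uses 650-690 nm.
#' @return Named numeric vector of the 13 parameters.
#' @export
edge_parameters <- function(s_raw, s_fd, sdr_window = c("red_edge", "red_well")) {
  sdr_window <- match.arg(sdr_window)
  if (n_samples(s_raw) != 1L || n_samples(s_fd) != 1L)
    stop("edge_parameters expects single spectra")
  blue <- window_slice(s_fd, 490, 530)
  yellow <- window_slice(s_fd, 560, 640)
  red <- window_slice(s_fd, 680, 760)
  green <- window_slice(s_raw, 510, 560)
  well <- window_slice(s_raw, 650, 690)
  sdr <- if (sdr_window == "red_edge") red else window_slice(s_fd, 650, 690)
  c(Db = max(blue$v), lambda_b = blue$wl[which.max(blue$v)],
    Dy = max(yellow$v), lambda_y = yellow$wl[which.max(yellow$v)],
    Dr = max(red$v), lambda_r = red$wl[which.max(red$v)],
    Rg = max(green$v), lambda_g = green$wl[which.max(green$v)],
    Ro = min(well$v), lambda_o = well$wl[which.min(well$v)],
    SDb = pracma::trapz(blue$wl, blue$v),
    SDy = pracma::trapz(yellow$wl, yellow$v),
    SDr = pracma::trapz(sdr$wl, sdr$v))
}

#' Canonical names of the 40 position features
#' @return Character vector of length 40 in the fixed serialization order.
#' @export
position_feature_names <- function() {
  c(as.vector(outer(paste0("A_", c("Depth", "Area", "ND")), 1:3,
                    paste, sep = "_")),
    as.vector(outer(paste0("R_", c("Depth", "Area", "ND")), 1:6,
                    paste, sep = "_")),
    names(edge_parameters(
      spectrum_set(400:800, matrix(seq(0.1, 0.5, length.out = 401), 1)),
      spectrum_set(400:800, matrix(0.001, 1, 401)))))
}

#' Position feature table
#'
#' Computes the full 40-value position feature vector per sample: depth,
#' area and normalized depth for the 3 absorption and 6 reflection regions
#' (9 + 18 values) plus the 13 edge/peak parameters.
#'
#' @param s_raw `spectrum_set` of smoothed, masked reflectance.
#' @param s_fd `spectrum_set` of masked first-derivative values; computed
#'   from `s_raw` when `NULL` (note: derive before masking where possible so
#'   interval borders do not create spurious differences).
#' @param sdr_window Passed to [edge_parameters()].
#' @return Numeric matrix samples x 40 with canonical column names.
#' @export
position_features <- function(s_raw, s_fd = NULL, sdr_window = "red_edge") {
  if (is.null(s_fd)) s_fd <- first_derivative(s_raw)
  regions <- c(absorption_regions(), reflection_regions())
  out <- t(vapply(seq_len(n_samples(s_raw)), function(i) {
    si <- get_spectrum(s_raw, i)
    fi <- get_spectrum(s_fd, s_raw$sample_ids[i])
    vals <- unlist(lapply(regions, function(rg) {
      if (rg$kind == "absorption") absorption_features(si, rg)
      else reflection_features(si, rg)
    }))
    c(vals, edge_parameters(si, fi, sdr_window))
  }, numeric(40)))
  colnames(out) <- position_feature_names()
  rownames(out) <- s_raw$sample_ids
  out
}

#' Units of the 40 position features
#' @return Named character vector mapping feature name to unit.
#' @export
position_feature_units <- function() {
  nm <- position_feature_names()
  u <- ifelse(grepl("_Area_", nm), "nm",
       ifelse(grepl("_ND_", nm), "nm^-1",
       ifelse(grepl("^lambda", nm), "nm",
       ifelse(nm %in% c("Db", "Dy", "Dr"), "nm^-1",
       ifelse(nm %in% c("SDb", "SDy", "SDr"), "unitless (integrated nm^-1 * nm)",
              "unitless")))))
  stats::setNames(u, nm)
}

#' Write a position feature table with a units sidecar
#' @param feats Matrix from [position_features()].
#' @param path CSV output path; a `<path>.units.json` sidecar is written too.
#' @return Invisibly, `path`.
#' @export
write_position_features <- function(feats, path) {
  utils::write.csv(data.frame(sample_id = rownames(feats), feats,
                              check.names = FALSE),
                   path, row.names = FALSE)
  jsonlite::write_json(as.list(position_feature_units()),
                       paste0(path, ".units.json"), auto_unbox = TRUE)
  invisible(path)
}
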