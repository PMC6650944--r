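#' Spectrum set container
#'
#' Bundles a shared wavelength grid (nm) with a samples-by-wavelengths
#' reflectance matrix. All downstream feature extraction operates on this
#' container.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly increasing.
#' @param reflectance Numeric matrix, one row per sample, one column per
#'   wavelength. Reflectance is a unitless fraction.
#' @param sample_ids Character vector of unique sample labels (defaults to the
#'   rownames of `reflectance`).
#' @return An object of class `spectrum_set`: a list with elements
#'   `wavelengths`, `reflectance` (rownames = sample ids) and `sample_ids`.
#' @export
spectrum_set <- function(wavelengths, reflectance, sample_ids = rownames(reflectance)) {
  wavelengths <- as.numeric(wavelengths)
  if (is.vector(reflectance)) reflectance <- matrix(reflectance, nrow = 1)
  reflectance <- as.matrix(reflectance)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(reflectance)))
  sample_ids <- as.character(sample_ids)
  if (length(wavelengths) != ncol(reflectance))
    stop("ncol(reflectance) must equal length(wavelengths)")
  if (length(sample_ids) != nrow(reflectance))
    stop("one sample id per spectrum required")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids")
  if (any(!is.finite(wavelengths)) || any(diff(wavelengths) <= 0))
    stop("wavelengths must be finite and strictly increasing")
  if (any(!is.finite(reflectance)))
    stop("non-finite reflectance values")
  rownames(reflectance) <- sample_ids
  colnames(reflectance) <- NULL
  structure(list(wavelengths = wavelengths,
                 reflectance = reflectance,
                 sample_ids = sample_ids),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d wavelengths [%.1f, %.1f] nm\n",
              nrow(x$reflectance), length(x$wavelengths),
              min(x$wavelengths), max(x$wavelengths)))
  invisible(x)
}

#' Number of samples in a spectrum set
#' @param s A `spectrum_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(s) nrow(s$reflectance)

#' Linearly resample a spectrum set onto a 1 nm grid
#'
#' Field spectroradiometers sample at non-integer native resolution below
#' 1000 nm; a single integer-nm grid simplifies region integrals and band
#' lookup, so all spectra are interpolated at read time.
#'
#' @param s A `spectrum_set`.
#' @param step Grid step in nm (default 1).
#' @return A `spectrum_set` on the regular grid spanning the input range.
#' @export
resample_grid <- function(s, step = 1) {
  lo <- ceiling(min(s$wavelengths))
  hi <- floor(max(s$wavelengths))
  grid <- seq(lo, hi, by = step)
  if (isTRUE(all.equal(grid, s$wavelengths))) return(s)
  m <- t(apply(s$reflectance, 1L, function(r)
    stats::approx(s$wavelengths, r, xout = grid)$y))
  spectrum_set(grid, m, s$sample_ids)
}

#' Read spectra and LNC tables from CSV
#'
#' The spectra file has a header `wavelength,<id1>,<id2>,...` and one row per
#' wavelength; the LNC file has columns `sample_id,lnc` (LNC in % dry mass).
#' Samples present in only one of the two files are reported and dropped.
#' Reflectance supplied in percent (values above 1.5) is auto-detected and
#' divided by 100; isolated values outside [-0.05, 1.5] trigger a warning and
#' are clamped into [0, 1].
#'
#' @param path Path to the spectra CSV.
#' @param lnc_path Path to the LNC CSV.
#' @param resample If `TRUE` (default) interpolate onto a 1 nm grid.
#' @return A list with `spectra` (a `spectrum_set`) and `lnc` (a data.frame
#'   with `sample_id` and `lnc`, row order matching the spectra).
#' @export
read_spectra <- function(path, lnc_path, resample = TRUE) {
  if (!file.exists(path)) stop("spectra file not found: ", path)
  if (!file.exists(lnc_path)) stop("LNC file not found: ", lnc_path)
  raw <- utils::read.csv(path, check.names = FALSE)
  if (ncol(raw) < 2) stop("spectra CSV needs a wavelength column plus samples")
  wl <- as.numeric(raw[[1]])
  if (any(diff(wl) <= 0)) stop("wavelengths must be strictly increasing")
  m <- t(as.matrix(raw[, -1, drop = FALSE]))
  ids <- colnames(raw)[-1]
  if (max(m, na.rm = TRUE) > 1.5) {
    message("reflectance looks like percent (max > 1.5); dividing by 100")
    m <- m / 100
  }
  bad <- m < -0.05 | m > 1.5
  if (any(bad)) {
    warning(sum(bad), " reflectance values outside [-0.05, 1.5]; clamped to [0, 1]")
    m <- pmin(pmax(m, 0), 1)
  }
  lnc <- utils::read.csv(lnc_path, check.names = FALSE)
  if (!all(c("sample_id", "lnc") %in% names(lnc)))
    stop("LNC CSV must have columns sample_id,lnc")
  lnc$sample_id <- as.character(lnc$sample_id)
  common <- intersect(ids, lnc$sample_id)
  dropped <- union(setdiff(ids, common), setdiff(lnc$sample_id, common))
  if (length(dropped))
    message("dropping samples present in only one file: ",
            paste(dropped, collapse = ", "))
  if (!length(common)) stop("no samples shared between spectra and LNC files")
  m <- m[match(common, ids), , drop = FALSE]
  s <- spectrum_set(wl, m, common)
  if (resample) s <- resample_grid(s)
  lnc <- lnc[match(common, lnc$sample_id), c("sample_id", "lnc")]
  rownames(lnc) <- NULL
  list(spectra = s, lnc = lnc)
}

#' Write a spectrum set and LNC table to CSV
#'
#' Emits the same dialects [read_spectra()] consumes.
#'
#' @param s A `spectrum_set`.
#' @param lnc Data frame with `sample_id` and `lnc`, or `NULL` to skip.
#' @param path Output path for the spectra CSV.
#' @param lnc_path Output path for the LNC CSV (required when `lnc` given).
#' @return Invisibly, `path`.
#' @export
write_spectra <- function(s, lnc = NULL, path, lnc_path = NULL) {
  df <- data.frame(wavelength = s$wavelengths, t(s$reflectance),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(lnc)) {
    if (is.null(lnc_path)) stop("lnc_path required when writing LNC")
    utils::write.csv(lnc[, c("sample_id", "lnc")], lnc_path, row.names = FALSE)
  }
  invisible(path)
}

# Hat vectors for the truncated one-sided polynomial fits used at the
# spectrum ends: fitted value at position i from the window idx.
sg_edge_hat <- function(i, idx, polyorder) {
  X <- outer(idx - i, 0:polyorder, `^`)
  xi <- (i - i)^(0:polyorder) # c(1, 0, 0, ...)
  as.numeric(xi %*% solve(crossprod(X), t(X)))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing on the uniform wavelength grid.
#' Interior points use the standard convolution weights; at each spectrum end
#' the polynomial is refit on the truncated window actually available (no
#' padding), so edge values never use invented data.
#'
#' @param s A `spectrum_set` on a uniform grid.
#' @param window Odd moving-window width in grid points (default 17).
#' @param polyorder Polynomial degree (default 2); must be < `window`.
#' @return A smoothed `spectrum_set` on the same grid.
#' @export
sg_smooth <- function(s, window = 17, polyorder = 2) {
  stopifnot(inherits(s, "spectrum_set"))
  n <- length(s$wavelengths)
  if (window %% 2 != 1) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be less than window")
  if (window >= n) stop("window must be shorter than the spectrum")
  h <- (window - 1L) / 2L
  w <- signal::sgolay(p = polyorder, n = window)[h + 1L, ]
  sm <- t(apply(s$reflectance, 1L, function(r)
    stats::filter(r, w, sides = 2)))
  # truncated-window refits at the two ends
  for (i in seq_len(h)) {
    idx_l <- 1L:min(n, i + h)
    sm[, i] <- s$reflectance[, idx_l, drop = FALSE] %*%
      sg_edge_hat(i, idx_l, polyorder)
    j <- n - i + 1L
    idx_r <- max(1L, j - h):n
    sm[, j] <- s$reflectance[, idx_r, drop = FALSE] %*%
      sg_edge_hat(j, idx_r, polyorder)
  }
  spectrum_set(s$wavelengths, sm, s$sample_ids)
}

#' First-derivative spectra
#'
#' Finite difference of reflectance with respect to wavelength,
#' `(R(j+1) - R(j)) / (lambda(j+1) - lambda(j))` in nm^-1, assigned to the
#' midpoint between consecutive wavebands. The output grid therefore has one
#' fewer point than the input.
#'
#' @param s A `spectrum_set`.
#' @return A `spectrum_set` of derivative values on the midpoint grid.
#' @export
first_derivative <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  wl <- s$wavelengths
  if (length(wl) < 2) stop("need at least 2 wavelengths")
  dl <- diff(wl)
  fd <- t(apply(s$reflectance, 1L, diff)) / rep(dl, each = nrow(s$reflectance))
  if (nrow(s$reflectance) == 1L) fd <- matrix(diff(s$reflectance[1L, ]) / dl, nrow = 1)
  mid <- (wl[-length(wl)] + wl[-1]) / 2
  spectrum_set(mid, fd, s$sample_ids)
}

#' Wavelength mask of atmospheric transmission windows
#'
#' Water vapor contaminates field reflectance outside a few transparent
#' windows; the default keeps 400-1353, 1437-1799 and 1992-2354 nm.
#'
#' @param kept_intervals List of `c(lo, hi)` closed intervals in nm.
#' @return An object of class `wavelength_mask`.
#' @export
wavelength_mask <- function(kept_intervals = list(c(400, 1353),
                                                  c(1437, 1799),
                                                  c(1992, 2354))) {
  kept_intervals <- lapply(kept_intervals, as.numeric)
  if (!length(kept_intervals)) stop("mask needs at least one interval")
  if (any(vapply(kept_intervals, function(iv)
    length(iv) != 2 || iv[1] > iv[2], logical(1))))
    stop("each interval must be c(lo, hi) with lo <= hi")
  o <- order(vapply(kept_intervals, `[`, numeric(1), 1L))
  kept_intervals <- kept_intervals[o]
  los <- vapply(kept_intervals, `[`, numeric(1), 1L)
  his <- vapply(kept_intervals, `[`, numeric(1), 2L)
  if (any(los[-1] <= his[-length(his)])) stop("intervals must be disjoint")
  structure(list(kept_intervals = kept_intervals), class = "wavelength_mask")
}

#' Test wavelengths against a mask
#' @param wl Numeric wavelengths in nm.
#' @param mask A `wavelength_mask`.
#' @return Logical vector, `TRUE` where kept.
#' @export
in_mask <- function(wl, mask) {
  keep <- rep(FALSE, length(wl))
  for (iv in mask$kept_intervals) keep <- keep | (wl >= iv[1] & wl <= iv[2])
  keep
}

#' Drop masked wavelengths from a spectrum set
#'
#' @param s A `spectrum_set`.
#' @param mask A `wavelength_mask` (default: the water-vapor windows).
#' @return A `spectrum_set` restricted to the kept intervals; wavelength
#'   order is preserved.
#' @export
apply_mask <- function(s, mask = wavelength_mask()) {
  stopifnot(inherits(s, "spectrum_set"), inherits(mask, "wavelength_mask"))
  keep <- in_mask(s$wavelengths, mask)
  if (!any(keep)) stop("mask removes every wavelength")
  spectrum_set(s$wavelengths[keep], s$reflectance[, keep, drop = FALSE],
               s$sample_ids)
}

#' Extract one sample as a single-spectrum set
#' @param s A `spectrum_set`.
#' @param id Sample id or row index.
#' @return A one-row `spectrum_set`.
#' @export
get_spectrum <- function(s, id) {
  i <- if (is.character(id)) match(id, s$sample_ids) else as.integer(id)
  if (is.na(i) || i < 1 || i > n_samples(s)) stop("unknown sample: ", id)
  spectrum_set(s$wavelengths, s$reflectance[i, , drop = FALSE], s$sample_ids[i])
}
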