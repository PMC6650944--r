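# Shared fixture builders: all fixtures are generated in code at test time.

# spectrum set from a function of wavelength, one row per sample
fun_set <- function(f, wl = 400:900, ids = "S1") {
  m <- do.call(rbind, lapply(seq_along(ids), function(i) f(wl)))
  spectrum_set(wl, m, ids)
}

# piecewise-linear spectrum through (wavelength, reflectance) anchor points
anchor_set <- function(anchors, wl = 400:900, id = "S1") {
  f <- stats::approxfun(anchors[, 1], anchors[, 2], rule = 2)
  fun_set(f, wl, id)
}

# V-shaped dip / peak on a synthetic 0..10 nm axis
vee_set <- function(endpoint, apex, up = FALSE) {
  wl <- 0:10
  r <- endpoint + (apex - endpoint) * (1 - abs(wl - 5) / 5)
  spectrum_set(wl, matrix(r, 1), "S1")
}

# write a toy spectra + LNC CSV pair; returns the two paths
write_toy_csvs <- function(dir, wl = 400:900, ids = c("a", "b", "c"),
                           lnc_ids = ids) {
  set.seed(99)
  m <- sapply(ids, function(i) 0.2 + 0.1 * sin(wl / 50) + stats::runif(1, 0, 0.1))
  sp <- file.path(dir, "spectra.csv")
  utils::write.csv(data.frame(wavelength = wl, m, check.names = FALSE),
                   sp, row.names = FALSE)
  ln <- file.path(dir, "lnc.csv")
  utils::write.csv(data.frame(sample_id = lnc_ids,
                              lnc = seq(1, 2, length.out = length(lnc_ids))),
                   ln, row.names = FALSE)
  c(spectra = sp, lnc = ln)
}

# small standardized random design matrix with named columns
rand_design <- function(n, p, seed) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  colnames(X) <- sprintf("x%02d", seq_len(p))
  X
}

# brute-force residual norm of `col` orthogonal to span(S), via lm
bf_residual_norm <- function(col, S) {
  if (is.null(S) || ncol(S) == 0) return(sqrt(sum(col^2)))
  sqrt(sum(stats::resid(stats::lm(col ~ 0 + S))^2))
}
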