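#' Broadband configuration
#'
#' Wavelength intervals used as surrogates for multispectral sensor bands
#' when an index is defined on broadband reflectances. Band reflectance is
#' the unweighted mean over the interval (no sensor response functions are
#' published for this workflow, so flat responses over conventional band
#' limits are used; all intervals are configurable).
#'
#' @param B,G,R,RedEdge,NIR `c(lo, hi)` intervals in nm.
#' @return An object of class `broadband_config`.
#' @export
broadband_config <- function(B = c(450, 520), G = c(520, 600), R = c(630, 690),
                             RedEdge = c(705, 745), NIR = c(760, 900)) {
  bands <- list(B = B, G = G, R = R, RedEdge = RedEdge, NIR = NIR)
  for (nm in names(bands))
    if (length(bands[[nm]]) != 2 || bands[[nm]][1] > bands[[nm]][2])
      stop("band ", nm, " must be c(lo, hi)")
  structure(bands, class = "broadband_config")
}

#' Narrowband reflectance lookup
#'
#' Reflectance at the grid point nearest the requested wavelength (exact on
#' the 1 nm working grid). Errors if the nearest available point is more than
#' 2 nm away, which happens when the wavelength falls in a masked window.
#'
#' @param s A `spectrum_set`.
#' @param lambda Wavelength in nm.
#' @return Numeric vector of reflectances, one per sample.
#' @export
narrowband <- function(s, lambda) {
  i <- which.min(abs(s$wavelengths - lambda))
  if (abs(s$wavelengths[i] - lambda) > 2)
    stop("wavelength ", lambda, " nm is masked or outside the grid")
  s$reflectance[, i]
}

#' Broadband reflectance
#'
#' Unweighted mean reflectance over a configured band interval.
#'
#' @param s A `spectrum_set`.
#' @param band One of `"B"`, `"G"`, `"R"`, `"RedEdge"`, `"NIR"`.
#' @param cfg A `broadband_config`.
#' @return Numeric vector, one value per sample.
#' @export
broadband <- function(s, band, cfg = broadband_config()) {
  iv <- cfg[[band]]
  if (is.null(iv)) stop("unknown band: ", band)
  idx <- which(s$wavelengths >= iv[1] & s$wavelengths <= iv[2])
  if (!length(idx)) stop("band ", band, " does not overlap the grid")
  rowMeans(s$reflectance[, idx, drop = FALSE])
}

# Division that propagates an undefined-value marker (NA) on (near-)zero
# denominators instead of throwing; callers log how many samples were hit.
safe_div <- function(num, den, eps = 1e-12) {
  out <- num / den
  out[abs(den) < eps] <- NA_real_
  out
}

#' Vegetation index registry
#'
#' The 34 vegetation indices used by the workflow, in canonical order.
#' Narrowband indices use `R_<lambda>` reflectances; broadband indices use
#' the `broadband_config` surrogates. Three published index rows are
#' typographically degenerate as printed (GNDVI with the red instead of the
#' green band; red-edge NDVI with a minus in the denominator, identically 1;
#' MTCI printed as `(NIR - RE)/(RE - NIR)`, identically -1). The default
#' `"corrected"` mode implements the standard literature forms; mode
#' `"paper_literal"` evaluates those three rows exactly as printed. All other
#' rows are identical in the two modes.
#'
#' @param mode `"corrected"` (default) or `"paper_literal"`.
#' @return Named list of functions `f(nb, bb)` where `nb(lambda)` returns
#'   narrowband and `bb(band)` broadband reflectance vectors; the list also
#'   carries a `"formulas"` attribute of human-readable formula strings.
#' @export
vi_registry <- function(mode = c("corrected", "paper_literal")) {
  mode <- match.arg(mode)
  defs <- list()
  form <- character()
  add <- function(name, formula, fun) {
    defs[[name]] <<- fun
    form[name] <<- formula
  }

  add("Vi_opt", "1.45*(R800^2 + 1)/(R670 + 0.45)",
      function(nb, bb) (1 + 0.45) * (nb(800)^2 + 1) / (nb(670) + 0.45))
  add("NDVI_g-b#", "(R573 - R440)/(R573 + R440)",
      function(nb, bb) safe_div(nb(573) - nb(440), nb(573) + nb(440)))
  add("RVI_I#", "R810/R660", function(nb, bb) safe_div(nb(810), nb(660)))
  add("RVI_II#", "R810/R560", function(nb, bb) safe_div(nb(810), nb(560)))
  add("MCARI/MTVI2", "MCARI/MTVI2 (narrowband, as printed)",
      function(nb, bb) {
        mcari <- (nb(700) - nb(670) - 0.2 * (nb(700) - nb(550))) *
          safe_div(nb(700), nb(670))
        mtvi2 <- safe_div(1.5 * (1.2 * (nb(800) - nb(550))),
                          sqrt(pmax((2 * nb(800) + 1)^2 -
                                      (6 * nb(800) - 5 * sqrt(nb(670))) - 0.5, 0)))
        safe_div(mcari, mtvi2)
      })
  add("DCNI#", "((R720 - R700)/(R700 - R670))/(R720 - R670 + 0.03)",
      function(nb, bb) safe_div(safe_div(nb(720) - nb(700), nb(700) - nb(670)),
                                nb(720) - nb(670) + 0.03))
  add("NDVI_I", "(R800 - R670)/(R800 + R670)",
      function(nb, bb) safe_div(nb(800) - nb(670), nb(800) + nb(670)))
  add("RVI_III", "R800/R670", function(nb, bb) safe_div(nb(800), nb(670)))
  add("DVI_I", "R800 - R670", function(nb, bb) nb(800) - nb(670))
  add("SAVI_I", "1.5*(R800 - R670)/(R800 + R670 + 0.5)",
      function(nb, bb) safe_div(1.5 * (nb(800) - nb(670)),
                                nb(800) + nb(670) + 0.5))
  add("NDRE", "(R790 - R720)/(R790 + R720)",
      function(nb, bb) safe_div(nb(790) - nb(720), nb(790) + nb(720)))
  add("ARVI", "(NIR - RB)/(NIR + RB), RB = R - (B - R)",
      function(nb, bb) {
        rb <- bb("R") - 1 * (bb("B") - bb("R"))
        safe_div(bb("NIR") - rb, bb("NIR") + rb)
      })
  add("DVI_II", "NIR - R", function(nb, bb) bb("NIR") - bb("R"))
  add("EVI", "2.5*(NIR - R)/(NIR + 6R - 7.5B + 1)",
      function(nb, bb) safe_div(2.5 * (bb("NIR") - bb("R")),
                                bb("NIR") + 6 * bb("R") - 7.5 * bb("B") + 1))
  if (mode == "corrected")
    add("GNDVI", "(NIR - G)/(NIR + G)",
        function(nb, bb) safe_div(bb("NIR") - bb("G"), bb("NIR") + bb("G")))
  else
    add("GNDVI", "(NIR - R)/(NIR + R)  [as printed]",
        function(nb, bb) safe_div(bb("NIR") - bb("R"), bb("NIR") + bb("R")))
  add("MNLI", "1.5*(NIR^2 - R)/(NIR^2 + R + 0.5)",
      function(nb, bb) safe_div(1.5 * (bb("NIR")^2 - bb("R")),
                                bb("NIR")^2 + bb("R") + 0.5))
  add("MSAVI2", "(2NIR + 1 - sqrt((2NIR + 1)^2 - 8(NIR - R)))/2",
      function(nb, bb) (2 * bb("NIR") + 1 -
                          sqrt(pmax((2 * bb("NIR") + 1)^2 -
                                      8 * (bb("NIR") - bb("R")), 0))) / 2)
  add("MSR", "(NIR/R - 1)/(NIR/R + 1)",
      function(nb, bb) {
        sr <- safe_div(bb("NIR"), bb("R"))
        safe_div(sr - 1, sr + 1)
      })
  add("NDVI_II", "(NIR - R)/(NIR + R)",
      function(nb, bb) safe_div(bb("NIR") - bb("R"), bb("NIR") + bb("R")))
  add("NLI", "(NIR^2 - R)/(NIR^2 + R)",
      function(nb, bb) safe_div(bb("NIR")^2 - bb("R"), bb("NIR")^2 + bb("R")))
  add("OSAVI", "1.16*(NIR - R)/(NIR + R + 0.16)",
      function(nb, bb) safe_div((1 + 0.16) * (bb("NIR") - bb("R")),
                                bb("NIR") + bb("R") + 0.16))
  add("RDVI", "(NIR - R)/sqrt(NIR + R)",
      function(nb, bb) safe_div(bb("NIR") - bb("R"),
                                sqrt(pmax(bb("NIR") + bb("R"), 0))))
  add("RVI_IV", "NIR/R", function(nb, bb) safe_div(bb("NIR"), bb("R")))
  add("SAVI_II", "1.5*(NIR - R)/(NIR + R + 0.5)",
      function(nb, bb) safe_div(1.5 * (bb("NIR") - bb("R")),
                                bb("NIR") + bb("R") + 0.5))
  add("TVI", "60*(NIR - G) - 100*(R - G)",
      function(nb, bb) 60 * (bb("NIR") - bb("G")) - 100 * (bb("R") - bb("G")))
  add("MTVI2", "1.5*(1.2(NIR - G) - 2.5(R - G))/sqrt((2NIR + 1)^2 - (6NIR - 5 sqrt(R)) - 0.5)",
      function(nb, bb) safe_div(1.5 * (1.2 * (bb("NIR") - bb("G")) -
                                         2.5 * (bb("R") - bb("G"))),
                                sqrt(pmax((2 * bb("NIR") + 1)^2 -
                                            (6 * bb("NIR") - 5 * sqrt(bb("R"))) - 0.5, 0))))
  if (mode == "corrected")
    add("NDVI_Red-edge", "(NIR - RE)/(NIR + RE)",
        function(nb, bb) safe_div(bb("NIR") - bb("RedEdge"),
                                  bb("NIR") + bb("RedEdge")))
  else
    add("NDVI_Red-edge", "(NIR - RE)/(NIR - RE)  [as printed]",
        function(nb, bb) safe_div(bb("NIR") - bb("RedEdge"),
                                  bb("NIR") - bb("RedEdge")))
  add("CI_Red-edge", "NIR/RE - 1",
      function(nb, bb) safe_div(bb("NIR"), bb("RedEdge")) - 1)
  if (mode == "corrected")
    add("MTCI", "(NIR - RE)/(RE - R)",
        function(nb, bb) safe_div(bb("NIR") - bb("RedEdge"),
                                  bb("RedEdge") - bb("R")))
  else
    add("MTCI", "(NIR - RE)/(RE - NIR)  [as printed]",
        function(nb, bb) safe_div(bb("NIR") - bb("RedEdge"),
                                  bb("RedEdge") - bb("NIR")))
  add("WI", "R900/R970", function(nb, bb) safe_div(nb(900), nb(970)))
  add("NDWI", "(R860 - R1240)/(R860 + R1240)",
      function(nb, bb) safe_div(nb(860) - nb(1240), nb(860) + nb(1240)))
  add("NDII", "(R819 - R1600)/(R819 + R1600)",
      function(nb, bb) safe_div(nb(819) - nb(1600), nb(819) + nb(1600)))
  add("DSWI", "(R803 - R549)/(R1659 + R681)",
      function(nb, bb) safe_div(nb(803) - nb(549), nb(1659) + nb(681)))
  add("sLAIDI*", "s*(R1050 - R1250)/((R1050 + R1250)*R1555), s = 1",
      function(nb, bb) safe_div(1 * (nb(1050) - nb(1250)),
                                (nb(1050) + nb(1250)) * nb(1555)))

  attr(defs, "formulas") <- form
  attr(defs, "mode") <- mode
  defs
}

#' Audit the vegetation index registry
#'
#' Asserts the registry holds exactly 34 uniquely named definitions; called
#' at the top of [compute_indices()] so an incomplete registry fails fast.
#'
#' @param registry Output of [vi_registry()].
#' @return Invisibly `TRUE`; errors on any violation.
#' @export
vi_registry_audit <- function(registry = vi_registry()) {
  nms <- names(registry)
  if (length(nms) != 34) stop("registry must hold 34 indices, found ", length(nms))
  if (anyDuplicated(nms)) stop("duplicate index names in registry")
  if (length(attr(registry, "formulas")) != 34) stop("missing formula strings")
  invisible(TRUE)
}

#' Compute one vegetation index
#'
#' @param s A `spectrum_set`.
#' @param name Index name as in [vi_registry()].
#' @param cfg A `broadband_config`.
#' @param registry Registry to draw the definition from.
#' @return Numeric vector, one value per sample (`NA` marks an undefined
#'   value from a zero denominator).
#' @export
compute_index <- function(s, name, cfg = broadband_config(),
                          registry = vi_registry()) {
  f <- registry[[name]]
  if (is.null(f)) stop("unknown vegetation index: ", name)
  nb <- function(lambda) narrowband(s, lambda)
  bb_cache <- new.env(parent = emptyenv())
  bb <- function(band) {
    if (is.null(bb_cache[[band]])) bb_cache[[band]] <- broadband(s, band, cfg)
    bb_cache[[band]]
  }
  out <- f(nb, bb)
  if (anyNA(out))
    message("index ", name, ": ", sum(is.na(out)),
            " sample(s) undefined (zero denominator)")
  out
}

#' Compute the full vegetation index table
#'
#' @param s A `spectrum_set`.
#' @param cfg A `broadband_config`.
#' @param mode Registry mode, see [vi_registry()].
#' @return Numeric matrix samples x 34, columns in canonical registry order.
#' @export
compute_indices <- function(s, cfg = broadband_config(),
                            mode = c("corrected", "paper_literal")) {
  registry <- vi_registry(match.arg(mode))
  vi_registry_audit(registry)
  out <- vapply(names(registry), function(nm)
    compute_index(s, nm, cfg, registry), numeric(n_samples(s)))
  if (n_samples(s) == 1L) out <- matrix(out, nrow = 1,
                                        dimnames = list(NULL, names(registry)))
  rownames(out) <- s$sample_ids
  out
}

#' Dump the registry as JSON for provenance
#' @param path Output path.
#' @param mode Registry mode.
#' @return Invisibly, `path`.
#' @export
write_vi_registry <- function(path, mode = "corrected") {
  reg <- vi_registry(mode)
  jsonlite::write_json(
    list(mode = mode,
         indices = lapply(names(reg), function(nm)
           list(name = nm, formula = unname(attr(reg, "formulas")[nm])))),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
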