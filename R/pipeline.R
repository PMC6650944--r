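#' Build the four feature families from raw spectra
#'
#' Applies the standard preprocessing (Savitzky-Golay smoothing, first
#' derivative, water-vapor masking) and derives the per-sample feature
#' matrices for the four families screened by the workflow:
#' \describe{
#'   \item{bands}{masked smoothed reflectance, one column per wavelength
#'     (`R_<nm>`)}
#'   \item{fd}{masked first-derivative spectrum on the midpoint grid
#'     (`FD_<nm>`)}
#'   \item{positions}{the 40 continuum-removal/edge position features}
#'   \item{vis}{the 34 vegetation indices}
#' }
#'
#' @param spectra A `spectrum_set` of raw reflectance.
#' @param mask A `wavelength_mask` (default: water-vapor windows).
#' @param bb_cfg A `broadband_config`.
#' @param vi_mode Vegetation-index registry mode.
#' @param sdr_window Passed to [position_features()].
#' @param sg_window,sg_polyorder Savitzky-Golay parameters (defaults 17, 2).
#' @return Named list of numeric matrices (`bands`, `fd`, `positions`,
#'   `vis`), all with sample-id rownames.
#' @export
feature_families <- function(spectra, mask = wavelength_mask(),
                             bb_cfg = broadband_config(),
                             vi_mode = "corrected",
                             sdr_window = "red_edge",
                             sg_window = 17, sg_polyorder = 2) {
  smooth <- sg_smooth(spectra, sg_window, sg_polyorder)
  fd_full <- first_derivative(smooth)
  sm_m <- apply_mask(smooth, mask)
  fd_m <- apply_mask(fd_full, mask)
  bands <- sm_m$reflectance
  colnames(bands) <- sprintf("R_%g", sm_m$wavelengths)
  fd <- fd_m$reflectance
  colnames(fd) <- sprintf("FD_%g", fd_m$wavelengths)
  list(bands = bands,
       fd = fd,
       positions = position_features(sm_m, fd_m, sdr_window = sdr_window),
       vis = compute_indices(sm_m, bb_cfg, mode = vi_mode))
}

# rows usable for modeling: no missing feature in the active family
complete_rows <- function(X) {
  ok <- stats::complete.cases(X)
  if (!all(ok))
    message("dropping ", sum(!ok), " sample(s) with undefined features")
  ok
}

#' Screen and model one feature family
#'
#' SPA variable selection on the calibration rows only (no validation
#' information flows into screening), then PLS and RF fits on the
#' calibration set evaluated on both sets.
#'
#' @param family Family label.
#' @param X Feature matrix (samples x variables, sample-id rownames).
#' @param lnc Data.frame `sample_id`, `lnc`.
#' @param split List with `calibration` and `validation` id vectors.
#' @param k_max Passed to [spa_select()].
#' @param rf_seed Seed for the random forest fit.
#' @param spa_on `"calibration"` (default, leakage-safe) or `"all"` to screen
#'   on the pooled samples.
#' @return List with `family`, `selection` (a `spa_selection`), `reports`
#'   (data.frame, 4 rows), `fits` and `predictions` (per set/algorithm).
#' @export
run_family <- function(family, X, lnc, split, k_max = NULL,
                       rf_seed = 20120731, spa_on = c("calibration", "all")) {
  spa_on <- match.arg(spa_on)
  if (ncol(X) < 2) stop("family ", family, " yields fewer than 2 features")
  y <- stats::setNames(lnc$lnc, lnc$sample_id)
  ok <- complete_rows(X)
  usable <- rownames(X)[ok]
  cal <- intersect(split$calibration, usable)
  val <- intersect(split$validation, usable)
  Xsel <- if (spa_on == "calibration") X[cal, , drop = FALSE] else
    X[c(cal, val), , drop = FALSE]
  ysel <- y[rownames(Xsel)]
  selection <- spa_select(Xsel, ysel, k_max = k_max)
  vars <- selection$selected
  Xc <- X[cal, vars, drop = FALSE]; yc <- y[cal]
  Xv <- X[val, vars, drop = FALSE]; yv <- y[val]
  pls <- fit_pls(Xc, yc)
  rf <- fit_rf(Xc, yc, seed = rf_seed)
  preds <- list(
    PLS = list(calibration = stats::predict(pls, Xc),
               validation = stats::predict(pls, Xv)),
    RF = list(calibration = stats::predict(rf, Xc),
              validation = stats::predict(rf, Xv)))
  reports <- do.call(rbind, lapply(names(preds), function(alg) {
    model_report(family, alg,
                 regression_metrics(yc, preds[[alg]]$calibration),
                 regression_metrics(yv, preds[[alg]]$validation),
                 length(yc), length(yv), yc, yv)
  }))
  list(family = family, selection = selection, reports = reports,
       fits = list(PLS = pls, RF = rf),
       predictions = preds,
       samples = list(calibration = cal, validation = val))
}

#' Screen and model the integrated variable set
#'
#' Pools every family's SPA-selected variables into one design matrix,
#' reruns SPA on the pool, and fits/evaluates PLS and RF as in
#' [run_family()].
#'
#' @param family_results Named list of [run_family()] outputs.
#' @param features Named list of family feature matrices (as from
#'   [feature_families()]).
#' @param lnc,split,k_max,rf_seed,spa_on As in [run_family()].
#' @return A [run_family()]-shaped list with `family = "integrated"` and the
#'   pooled variable count in `pool_size`.
#' @export
run_integrated <- function(family_results, features, lnc, split,
                           k_max = NULL, rf_seed = 20120731,
                           spa_on = "calibration") {
  pool <- do.call(cbind, lapply(names(family_results), function(f)
    features[[f]][, family_results[[f]]$selection$selected, drop = FALSE]))
  if (ncol(pool) < 2) stop("pooled matrix has fewer than 2 variables")
  res <- run_family("integrated", pool, lnc, split, k_max = k_max,
                    rf_seed = rf_seed, spa_on = spa_on)
  res$pool_size <- ncol(pool)
  res
}

#' Run the full LNC estimation workflow
#'
#' Preprocessing, feature extraction for the four families, SPA screening
#' per family, PLS/RF modeling, and the integrated rescreen, on a synthetic
#' dataset or on spectra read from disk.
#'
#' @param dataset A `synthetic_dataset`, or a list with `spectra` (a
#'   `spectrum_set`), `lnc` (data.frame) and optional `split`.
#' @param split Optional list `calibration`/`validation` of sample ids;
#'   defaults to the dataset's recorded split, else a seeded random 2:1 split.
#' @param split_seed Seed for the fallback split.
#' @param k_max,rf_seed,spa_on Passed to the screening/model stages.
#' @param mask,bb_cfg,vi_mode,sdr_window,sg_window,sg_polyorder Passed to
#'   [feature_families()].
#' @return An object of class `lnc_run`: list with `features`, `families`
#'   (per-family results), `integrated`, `reports` (combined data.frame) and
#'   `config`.
#' @export
run_lnc_pipeline <- function(dataset, split = NULL, split_seed = 1L,
                             k_max = NULL, rf_seed = 20120731,
                             spa_on = "calibration",
                             mask = wavelength_mask(),
                             bb_cfg = broadband_config(),
                             vi_mode = "corrected",
                             sdr_window = "red_edge",
                             sg_window = 17, sg_polyorder = 2) {
  spectra <- dataset$spectra
  lnc <- dataset$lnc
  if (is.null(split)) split <- dataset$split
  if (is.null(split)) {
    set.seed(split_seed)
    ids <- spectra$sample_ids
    cal <- sort(sample.int(length(ids), round(2 / 3 * length(ids))))
    split <- list(calibration = ids[cal], validation = ids[-cal])
  }
  features <- feature_families(spectra, mask = mask, bb_cfg = bb_cfg,
                               vi_mode = vi_mode, sdr_window = sdr_window,
                               sg_window = sg_window,
                               sg_polyorder = sg_polyorder)
  fams <- lapply(names(features), function(f)
    run_family(f, features[[f]], lnc, split, k_max = k_max,
               rf_seed = rf_seed, spa_on = spa_on))
  names(fams) <- names(features)
  integrated <- run_integrated(fams, features, lnc, split, k_max = k_max,
                               rf_seed = rf_seed, spa_on = spa_on)
  reports <- rbind(do.call(rbind, lapply(fams, `[[`, "reports")),
                   integrated$reports)
  rownames(reports) <- NULL
  structure(list(features = features, families = fams,
                 integrated = integrated, reports = reports,
                 split = split,
                 config = list(k_max = k_max, rf_seed = rf_seed,
                               spa_on = spa_on, vi_mode = vi_mode,
                               sdr_window = sdr_window,
                               sg_window = sg_window,
                               sg_polyorder = sg_polyorder,
                               split_seed = split_seed)),
            class = "lnc_run")
}

#' @export
print.lnc_run <- function(x, ...) {
  cat("<lnc_run>\n")
  sel <- vapply(c(x$families, list(integrated = x$integrated)), function(f)
    paste(f$selection$selected, collapse = ", "), character(1))
  for (f in names(sel)) cat(sprintf("  %-10s -> %s\n", f, sel[f]))
  print(x$reports, digits = 3)
  invisible(x)
}

#' Measured-versus-predicted scatter data for the validation set
#' @param run An `lnc_run`.
#' @param lnc Data.frame `sample_id`, `lnc` with the observed values.
#' @param family Which result to extract (default `"integrated"`).
#' @return Data.frame `sample_id`, `algorithm`, `observed`, `predicted`.
#' @export
scatter_data <- function(run, lnc, family = "integrated") {
  res <- if (family == "integrated") run$integrated else run$families[[family]]
  y <- stats::setNames(lnc$lnc, lnc$sample_id)
  ids <- res$samples$validation
  do.call(rbind, lapply(c("PLS", "RF"), function(alg)
    data.frame(sample_id = ids, algorithm = alg, observed = unname(y[ids]),
               predicted = res$predictions[[alg]]$validation)))
}

#' Write run reports to disk
#'
#' Emits the combined report CSV (columns family, algorithm, set, n, r2,
#' rmse, nrmse), per-family selection JSON, validation scatter CSV and a run
#' manifest. The NRMSE = RMSE/mean identity is re-checked at write time.
#'
#' @param run An `lnc_run`.
#' @param dir Output directory (created if needed).
#' @param lnc Data.frame `sample_id`, `lnc` used for the scatter file and
#'   identity check.
#' @return Invisibly, `dir`.
#' @export
write_reports <- function(run, dir, lnc) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  y <- stats::setNames(lnc$lnc, lnc$sample_id)
  all_res <- c(run$families, list(integrated = run$integrated))
  for (res in all_res) {
    for (set in c("calibration", "validation")) {
      ys <- y[res$samples[[set]]]
      for (alg in c("PLS", "RF")) {
        row <- run$reports[run$reports$family == res$family &
                             run$reports$algorithm == alg &
                             run$reports$set == set, ]
        stopifnot(abs(row$nrmse - row$rmse / mean(ys)) < 1e-12)
      }
    }
  }
  utils::write.csv(run$reports, file.path(dir, "model_reports.csv"),
                   row.names = FALSE)
  sel <- lapply(all_res, function(res)
    list(selected = res$selection$selected, start = res$selection$start,
         k = res$selection$k, criterion = res$selection$criterion))
  jsonlite::write_json(sel, file.path(dir, "selections.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  scatter <- do.call(rbind, lapply(c("PLS", "RF"), function(alg) {
    ids <- run$integrated$samples$validation
    data.frame(sample_id = ids, algorithm = alg, observed = unname(y[ids]),
               predicted = run$integrated$predictions[[alg]]$validation)
  }))
  utils::write.csv(scatter, file.path(dir, "validation_scatter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(package_version = as.character(
                              utils::packageVersion("maizeLNC")),
                            config = run$config, split = run$split),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
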