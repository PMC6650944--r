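#!/usr/bin/env Rscript
# Stage 4: summarize the run written by 03_screen_and_fit.R — selected
# variables per family, per-set model quality, and a check of the
# NRMSE = RMSE / mean(observed) identity on the emitted tables.

suppressPackageStartupMessages(library(maizeLNC))

run_dir <- file.path("results", "run")
rep_ <- utils::read.csv(file.path(run_dir, "model_reports.csv"))
sel <- jsonlite::read_json(file.path(run_dir, "selections.json"))
lnc <- utils::read.csv(file.path("results", "data", "lnc.csv"))
manifest <- jsonlite::read_json(file.path("results", "data", "manifest.json"))
split <- lapply(manifest$split, unlist)
y <- stats::setNames(lnc$lnc, lnc$sample_id)

cat("== selected variables ==\n")
for (f in names(sel))
  cat(sprintf("  %-10s (k=%d): %s\n", f, sel[[f]]$k,
              paste(unlist(sel[[f]]$selected), collapse = ", ")))

cat("\n== validation performance ==\n")
val <- rep_[rep_$set == "validation", ]
print(val[order(val$rmse), ], row.names = FALSE, digits = 3)

# identity re-check against the observed LNC
for (i in seq_len(nrow(rep_))) {
  m <- mean(y[split[[rep_$set[i]]]])
  stopifnot(abs(rep_$nrmse[i] - rep_$rmse[i] / m) < 1e-8)
}
cat("\nNRMSE = RMSE / mean(observed) verified on all",
    nrow(rep_), "report rows\n")

scatter <- utils::read.csv(file.path(run_dir, "validation_scatter.csv"))
for (alg in unique(scatter$algorithm)) {
  s <- scatter[scatter$algorithm == alg, ]
  m <- regression_metrics(s$observed, s$predicted)
  cat(sprintf("integrated %s validation: R2 %.3f, RMSE %.3f, NRMSE %.1f%%\n",
              alg, m[["r2"]], m[["rmse"]], 100 * m[["nrmse"]]))
}
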