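#!/usr/bin/env Rscript
# Stage 3: the full workflow — SPA variable screening per feature family on
# the calibration samples, PLS and random-forest fits, and the integrated
# rescreen over the pooled selections. Reports, selections, the validation
# scatter table and the run manifest are written to results/run/.

suppressPackageStartupMessages(library(maizeLNC))

dat <- read_spectra(file.path("results", "data", "spectra.csv"),
                    file.path("results", "data", "lnc.csv"))
manifest <- jsonlite::read_json(file.path("results", "data", "manifest.json"))
split <- lapply(manifest$split, unlist)

run <- run_lnc_pipeline(list(spectra = dat$spectra, lnc = dat$lnc,
                             split = split))
print(run)
write_reports(run, file.path("results", "run"), dat$lnc)
cat("reports written to results/run\n")
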