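#!/usr/bin/env Rscript
# Stage 1: generate the default synthetic corn-canopy dataset
# (n = 72 samples, 48/24 calibration/validation split, 350-2500 nm at 1 nm)
# and serialize it under results/data/.

suppressPackageStartupMessages(library(maizeLNC))

seed <- 20190601L
cfg <- sim_config(seed = seed)
ds <- make_dataset(cfg)

out <- file.path("results", "data")
write_dataset(ds, out)
cat("wrote spectra.csv, lnc.csv, manifest.json to", out, "\n")
print(descriptive_stats(ds$lnc$lnc))
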