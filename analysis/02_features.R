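#!/usr/bin/env Rscript
# Stage 2: preprocess the spectra written by 01_simulate.R (Savitzky-Golay
# smoothing, first derivative, water-vapor masking) and derive the four
# feature families: masked bands, first-derivative bands, the 40 position
# features and the 34 vegetation indices. Tables land in results/features/.

suppressPackageStartupMessages(library(maizeLNC))

dat <- read_spectra(file.path("results", "data", "spectra.csv"),
                    file.path("results", "data", "lnc.csv"))
feats <- feature_families(dat$spectra)

out <- file.path("results", "features")
dir.create(out, showWarnings = FALSE, recursive = TRUE)
for (fam in c("bands", "fd", "vis")) {
  utils::write.csv(data.frame(sample_id = rownames(feats[[fam]]),
                              feats[[fam]], check.names = FALSE),
                   file.path(out, paste0(fam, ".csv")), row.names = FALSE)
}
write_position_features(feats$positions, file.path(out, "positions.csv"))
cat("feature matrices written to", out, ":\n")
print(vapply(feats, dim, integer(2)))
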