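#!/usr/bin/env Rscript

# Stage 1: simulate the field campaign.
#
# Generates the 87-leaf canopy dataset (22 east / 22 south / 22 west /
# 21 north) with SPAD drawn from a truncated normal matching the
# campaign's summary statistics (mean 45.8, SD 3.64, range 32.6-67.1),
# and writes the spectra + labels tables that the later stages read.

suppressPackageStartupMessages(library(pearspad))
dir.create("results", showWarnings = FALSE)

cfg <- synthetic_config(seed = 20250605L)
ds <- generate_dataset(cfg)

paths <- write_spectra(ds, "results/spectra.csv", "results/spectra_labels.csv")

print(ds)
spad <- ds$samples$spad
message(sprintf("direction counts: %s",
                paste(sprintf("%s=%d", names(table(ds$samples$direction)),
                              table(ds$samples$direction)), collapse = " ")))
message(sprintf("SPAD: mean %.1f, sd %.2f, CV %.2f%%, range [%.1f, %.1f]",
                mean(spad), sd(spad), sd(spad) / mean(spad) * 100,
                min(spad), max(spad)))
message("wrote ", paste(paths, collapse = " and "))
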