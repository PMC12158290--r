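#!/usr/bin/env Rscript

# Stage 2: the full estimation pipeline.
#
# Reads the simulated campaign from stage 1, then for each of the 12
# representations (R, 1/R, logR, their derivatives, L1-L3, H1-H3):
# smooths, screens every band against SPAD on the 60-sample modeling
# split, selects two separation-constrained sensitive bands, fits the
# calibration, and evaluates R^2/RMSE on both splits. Two model readings
# are written: the headline PLS path and the two-band OLS path that
# mirrors the classical per-transform equation tables.

suppressPackageStartupMessages(library(pearspad))
dir.create("results/profiles", recursive = TRUE, showWarnings = FALSE)
dir.create("results/scatter", recursive = TRUE, showWarnings = FALSE)

ds <- read_spectra("results/spectra.csv", "results/spectra_labels.csv")

for (method in c("pls", "two_band_ols")) {
  res <- run_pipeline(ds, pipeline_config(method = method))
  out <- sprintf("results/model_comparison_%s.csv", method)
  utils::write.csv(res$comparison, out, row.names = FALSE)
  message(sprintf("[%s] winner: %s (validation R^2 = %.3f, RMSE = %.3f) -> %s",
                  method, res$winner_tag,
                  res$comparison$r2_valid[res$comparison$transform_tag ==
                                            res$winner_tag],
                  res$comparison$rmse_valid[res$comparison$transform_tag ==
                                              res$winner_tag],
                  out))
  if (method == "pls") {
    for (tag in names(res$profiles)) {
      utils::write.csv(res$profiles[[tag]],
                       sprintf("results/profiles/correlation_%s.csv", tag),
                       row.names = FALSE)
      utils::write.csv(res$predictions[[tag]],
                       sprintf("results/scatter/predicted_%s.csv", tag),
                       row.names = FALSE)
    }
    write_model_json(res$models[[res$winner_tag]],
                     "results/winner_model.json")
    print(res)
  }
}
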