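#!/usr/bin/env Rscript
# Duplex selection of the external test set (25 of 125, ~20%) on the raw
# fingerprint spectra, shared by every model, followed by verification that
# the test set mirrors the full set's positive/negative ratios and covers
# the full purity range.

library(ftirpls)

spectra <- read_spectra("results/spectra.csv", "wide_csv")
labels <- read_sample_table("results/labels.csv", check_consistency = FALSE)

split <- duplex_split(spectra, n_test = 25)
ratio <- verify_split(split, labels, tolerance = 0.15)

writeLines(c("set,sample_id",
             paste("train", split$train_ids, sep = ","),
             paste("test", split$test_ids, sep = ",")),
           "results/split.csv")
write.csv(as.data.frame(ratio), "results/split_ratios.csv", row.names = FALSE)

print(split)
print(as.data.frame(ratio), row.names = FALSE)
cov <- attr(ratio, "purity_coverage")
cat(sprintf("purity coverage: test %.2f-%.2f%% vs full %.2f-%.2f%% m/m\n",
            100 * cov$test[1], 100 * cov$test[2],
            100 * cov$full[1], 100 * cov$full[2]))
if (any(ratio$flagged)) {
  cat("flagged compounds (test ratio off by > 0.15):",
      paste(ratio$compound[ratio$flagged], collapse = ", "), "\n")
} else cat("no compound's test ratio deviates by more than 0.15\n")
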