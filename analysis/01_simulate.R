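#!/usr/bin/env Rscript
# Generate the synthetic study set: 125 street-heroin-like ATR-FTIR spectra
# on the 2000-650 cm^-1 fingerprint axis with matching assay annotations,
# mirroring the composition structure of the bundled real assay panel
# (~5.6% heroin-negative, log-normal purity with median ~11% m/m,
# near-ubiquitous caffeine/acetaminophen, sparse codeine, rare methacetin).

library(ftirpls)

seed <- 7L
dir.create("results", showWarnings = FALSE)

gen <- generate_spectra(125, seed = seed)
write_spectra(gen$spectra, "results/spectra.csv")
write_sample_table(gen$samples, "results/labels.csv")

pos <- gen$samples$purity[gen$samples$diacetylmorphine]
cat(sprintf("wrote %d spectra (%d wavenumbers) to results/spectra.csv\n",
            nrow(gen$spectra$absorbance), length(gen$spectra$wavenumbers)))
cat(sprintf("heroin-negative samples: %d of 125\n",
            sum(!gen$samples$diacetylmorphine)))
cat(sprintf("purity of positives: median %.1f%%, range %.2f-%.2f%% m/m\n",
            100 * median(pos), 100 * min(pos), 100 * max(pos)))
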