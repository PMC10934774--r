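# Shared simulation scenarios.

# Strongly informative classification scenario: presence is nearly affine in
# the heroin band amplitude (purity concentrated around 0.33), negatives are
# plain and not rare, and instrument noise is low. Used where a property
# needs a clearly separable class structure.
informative_composition <- function() {
  composition_model(negative_rate = 0.15, confusable_rate = 0,
                    purity_meanlog = log(0.33), purity_sdlog = 0.12,
                    purity_range = c(0.22, 0.48))
}

low_noise <- function() {
  noise_model(additive_sd = 0.001, baseline_amplitude = 0.005,
              scatter_sdlog = 0.02)
}

no_noise <- function() {
  noise_model(additive_sd = 0, baseline_amplitude = 0, scatter_sdlog = 0)
}

# small deterministic spectra_set for unit tests
toy_spectra <- function(n = 5L, p = 24L, seed = 1L) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p), n, p),
              seq(2000, by = -4, length.out = p),
              paste0("T", seq_len(n)))
}
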