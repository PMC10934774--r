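#!/usr/bin/env Rscript
# Permutation-based overfitting check of the selected heroin presence model:
# the response is shuffled 50 times, the model configuration re-fitted per
# shuffle, and the real model's self-prediction and cross-validated
# residuals compared against each shuffled model's via the pairwise
# Wilcoxon signed-rank, sign and randomization-t statistics. The
# SSQY-vs-correlation points drive the classic diagnostic plot.

library(ftirpls)

spectra <- read_spectra("results/spectra.csv", "wide_csv")
labels <- read_sample_table("results/labels.csv", check_consistency = FALSE)
report <- read.csv("results/model_report.csv")
split <- read.csv("results/split.csv")

her <- report[report$compound == "diacetylmorphine", ]
cat(sprintf("selected heroin model: %s, %d factors\n",
            her$pretreatment, her$n_factors))

train_ids <- split$sample_id[split$set == "train"]
x_train <- subset_samples(spectra, train_ids)
y_train <- as.numeric(labels$diacetylmorphine[match(train_ids,
                                                    labels$sample_id)])

perm <- permutation_test(x_train, y_train, n_factors = her$n_factors,
                         preprocess = her$pretreatment,
                         mode = "discriminant",
                         n_permutations = 50, seed = 7L)
print(perm)
pv <- permutation_p_values(perm)
write.csv(data.frame(statistic = names(pv), p_value = pv),
          "results/permutation_pvalues.csv", row.names = FALSE)
write.csv(perm$ssqy_points, "results/permutation_ssqy.csv",
          row.names = FALSE)

if (all(pv < 0.05)) {
  cat("all six p-values < 0.05: the selected model is significantly\n",
      "better than chance relabellings - low overfitting risk\n", sep = "")
} else {
  cat("p-values above 0.05 present: the model's advantage over chance\n",
      "relabellings is not decisive at this sample size\n", sep = "")
}
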