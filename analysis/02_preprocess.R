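#!/usr/bin/env Rscript
# Preprocess the simulated cohort: complete-case filtering, binary/one-hot
# encoding, outcome-stratified 80/20 split, and 0-1 scaling fitted on the
# training set only (leakage-safe).
library(mosr)

seed <- 20260925
cohort <- read_cohort("results/cohort.csv")

cc <- complete_case_filter(cohort)
cat(sprintf("complete cases: %d of %d (%d excluded)\n",
            nrow(cc$table), nrow(cohort), cc$excluded_count))

fm <- encode_features(cc$table)
cat(sprintf("encoded: %d columns from %d source features\n",
            ncol(fm$X), length(unique(fm$info$source))))

split <- stratified_split(fm, fraction = 0.8, seed = seed)
pars <- scale_fit(split$train)
train <- scale_apply(split$train, pars)
test <- scale_apply(split$test, pars)
cat(sprintf("split: %d train (%d events) / %d test (%d events)\n",
            nrow(train$X), sum(train$y), nrow(test$X), sum(test$y)))

write_feature_matrix(train, "results/train_matrix")
write_feature_matrix(test, "results/test_matrix")
cat("written: results/train_matrix.{csv,json}, results/test_matrix.{csv,json}\n")
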