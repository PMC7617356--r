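#!/usr/bin/env Rscript
# Evaluate the selected model with the full assessment protocol: metric
# panel on training data, ten repeated runs on random 90% test subsets,
# calibration bins, and the train-vs-test consistency gap.
library(mosr)

seed <- 20260925
train <- read_feature_matrix("results/train_matrix")
test <- read_feature_matrix("results/test_matrix")
model <- read_model("results/final_model.txt")

p_train <- predict_probability(model$tree, train$X)
train_report <- metrics_report(train$y, p_train)
cat(sprintf("training: F1 %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
            train_report$f1, train_report$sensitivity,
            train_report$specificity, train_report$auc))

te <- repeated_test_eval(model, test$X, test$y, runs = 10, fraction = 0.9,
                         seed = seed)
cat("test (mean over 10 runs on 90% subsets):\n")
for (m in names(te$mean))
  cat(sprintf("  %-12s %.3f (sd %.3f)\n", m, te$mean[m], te$sd[m]))

gap <- overfit_gap(train_report, as.list(te$mean))
cat(sprintf("train-test F1 gap: %.3f\n", gap["f1"]))

runs <- te$runs
summary_row <- runs[1, ]
summary_row[] <- NA
summary_row[names(te$mean)] <- te$mean
runs <- rbind(runs, summary_row)
utils::write.csv(runs, "results/test_metrics.csv", row.names = FALSE)
utils::write.csv(calibration_bins(test$y, predict_probability(model$tree, test$X)),
                 "results/calibration_bins.csv", row.names = FALSE)
cat("written: results/test_metrics.csv, results/calibration_bins.csv\n")
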