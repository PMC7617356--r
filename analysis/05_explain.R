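#!/usr/bin/env Rscript
# Shapley attribution for the selected model: per-patient attributions on
# the probability scale, feature ranking by mean |attribution|, and effect
# directions (attribution-vs-value correlation).
library(mosr)

seed <- 20260925
train <- read_feature_matrix("results/train_matrix")
test <- read_feature_matrix("results/test_matrix")
model <- read_model("results/final_model.txt")

set.seed(substream_seed(seed, "background"))
bg_idx <- sample.int(nrow(train$X), min(100, nrow(train$X)))
rep_ <- shap_report(model, test$X, train$X[bg_idx, , drop = FALSE],
                    n_permutations = 100, seed = seed)
imp <- summarize_importance(rep_)

cat("top features by mean |attribution| (direction = corr(attribution, value)):\n")
print(head(imp, 10), row.names = FALSE)

utils::write.csv(cbind(patient_id = test$row_ids, as.data.frame(rep_$attributions)),
                 "results/shap_attributions.csv", row.names = FALSE)
utils::write.csv(imp, "results/shap_importance.csv", row.names = FALSE)
shap_plot_data(rep_, "results/shap_beeswarm.csv")
cat("written: results/shap_attributions.csv, results/shap_importance.csv, results/shap_beeswarm.csv\n")
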