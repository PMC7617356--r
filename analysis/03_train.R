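#!/usr/bin/env Rscript
# Evolve the multi-objective symbolic-regression classifier on the training
# matrix and select the final model by (AUC, sensitivity, specificity).
# Population and generations here are scaled down from the full protocol
# (300 x 500) to desktop size; pass MOSR_FULL=... style overrides by editing
# the params below if you want the long run.
library(mosr)

seed <- 20260925
train <- read_feature_matrix("results/train_matrix")

params <- evolution_params(population = 200, generations = 120,
                           max_depth = 10, seed = seed)
t0 <- Sys.time()
fit <- evolve(train, train$y, params)
cat(sprintf("evolved %d generations in %.0f s; final front: %d model(s)\n",
            params$generations, as.numeric(Sys.time() - t0, units = "secs"),
            length(fit$front)))
cat(sprintf("best training BCE %.4f, best training F1 %.4f\n",
            min(fit$history$best_bce), 1 - min(fit$history$best_f1c)))

sel <- select_final_model(fit$front, train$X, train$y)
cat("selected formula:\n  ", serialize_formula(sel$individual$tree), "\n")

write_model(sel$individual, "results/final_model.txt", params)
utils::write.csv(fit$history, "results/history.csv", row.names = FALSE)
utils::write.csv(sel$table, "results/front_models.csv", row.names = FALSE)
cat("written: results/final_model.txt, results/history.csv, results/front_models.csv\n")
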