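# End-to-end orchestration: simulate -> preprocess -> train -> evaluate ->
# explain, fully reproducible from one master seed. The numbered scripts
# under analysis/ are thin narrative drivers over this function.

#' Run the full modelling pipeline on a synthetic cohort
#'
#' Chains cohort simulation, complete-case filtering, encoding, stratified
#' 80/20 splitting, min-max scaling (fitted on the training set by default),
#' multi-objective evolution, final-model selection by (AUC, sensitivity,
#' specificity), repeated test-subset evaluation, and Shapley attribution.
#'
#' @param gen_config [generator_config()]; its `seed` is overridden by the
#'   `seed` argument's "simulate" substream.
#' @param evo_params [evolution_params()]; its `seed` is overridden by the
#'   "train" substream.
#' @param seed Master seed.
#' @param split_fraction Training fraction (default 0.8).
#' @param scale_on `"train"` (leakage-safe, default) or `"all"` (fit the
#'   0-1 scaling on the whole dataset before splitting).
#' @param eval_runs,eval_fraction Repeated test evaluation settings
#'   (defaults 10 runs on 90% subsets).
#' @param explain Compute the Shapley report on the test set (default TRUE).
#' @param background_size Background rows for attribution (default 100).
#' @param explain_patients Number of test patients to explain (seeded
#'   subsample; default 100).
#' @param n_permutations Permutations per patient when the model references
#'   more than 12 features (default 100).
#' @return list: `cohort`, `excluded_count`, `train`, `test`
#'   (`feature_matrix`es), `fit`, `model` (selected individual), `formula`,
#'   `train_report`, `test_eval`, `gap`, `shap`, `importance`, `seed`.
#' @export
run_pipeline <- function(gen_config = generator_config(),
                         evo_params = evolution_params(),
                         seed = 1,
                         split_fraction = 0.8,
                         scale_on = c("train", "all"),
                         eval_runs = 10, eval_fraction = 0.9,
                         explain = TRUE, background_size = 100,
                         explain_patients = 100, n_permutations = 100) {
  scale_on <- match.arg(scale_on)

  # simulate
  gen_config$seed <- substream_seed(seed, "simulate")
  cohort <- sample_cohort(gen_config)

  # preprocess
  cc <- complete_case_filter(cohort)
  fm <- encode_features(cc$table)
  if (scale_on == "all") fm <- scale_apply(fm, scale_fit(fm))
  split <- stratified_split(fm, fraction = split_fraction,
                            seed = substream_seed(seed, "split"))
  train <- split$train; test <- split$test
  if (scale_on == "train") {
    pars <- scale_fit(train)
    train <- scale_apply(train, pars)
    test <- scale_apply(test, pars)
  }

  # train + select
  evo_params$seed <- substream_seed(seed, "train")
  fit <- evolve(train, train$y, evo_params)
  sel <- select_final_model(fit$front, train$X, train$y,
                            threshold = evo_params$threshold)
  model <- sel$individual

  # evaluate
  train_report <- metrics_report(train$y,
                                 predict_probability(model$tree, train$X),
                                 evo_params$threshold)
  test_eval <- repeated_test_eval(model, test$X, test$y,
                                  runs = eval_runs, fraction = eval_fraction,
                                  seed = substream_seed(seed, "evaluate"),
                                  threshold = evo_params$threshold)
  gap <- overfit_gap(train_report, as.list(test_eval$mean))

  # explain
  shap <- NULL; importance <- NULL
  if (explain) {
    bg_idx <- with_seed(substream_seed(seed, "background"),
                        draw_(seq_len(nrow(train$X)),
                              min(background_size, nrow(train$X))))
    ex_idx <- with_seed(substream_seed(seed, "explain_rows"),
                        sort(draw_(seq_len(nrow(test$X)),
                                   min(explain_patients, nrow(test$X)))))
    shap <- shap_report(model, test$X[ex_idx, , drop = FALSE],
                        train$X[bg_idx, , drop = FALSE],
                        n_permutations = n_permutations,
                        seed = substream_seed(seed, "explain"))
    importance <- summarize_importance(shap)
  }

  list(cohort = cohort, excluded_count = cc$excluded_count,
       train = train, test = test, fit = fit, model = model,
       formula = serialize_formula(model$tree),
       selection_table = sel$table,
       train_report = train_report, test_eval = test_eval, gap = gap,
       shap = shap, importance = importance, seed = seed)
}
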