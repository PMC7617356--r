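# Assessment protocol: stratified folds, grid-search 10-fold CV with an
# inner 90/10 train/validation division, and repeated test-subset
# evaluation with averaged metrics.

#' Stratified fold assignment
#'
#' Deals each outcome class round-robin across `k` folds after a seeded
#' within-class shuffle, so every fold keeps both classes whenever each
#' class has at least `k` members.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids (1..k).
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  if (k < 2) stop("need at least 2 folds")
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    if (length(idx) < k)
      stop(sprintf(
        "class %s has %d members, fewer than %d folds; use fewer folds",
        cls, length(idx), k))
    idx <- with_seed(substream_seed(seed, paste0("fold_", cls)), shuffle_(idx))
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

# stratified index split of a subset (inner 90/10 division)
inner_division <- function(labels, idx, fraction, seed) {
  sub <- stratified_split(
    data.frame(death_1y = labels[idx]), fraction = fraction, seed = seed)
  list(train = idx[sub$train_idx], val = idx[sub$test_idx])
}

#' Grid-search k-fold cross-validation
#'
#' For every grid setting: `folds` stratified outer folds; inside each
#' fold's training portion a stratified `inner_fraction` / complement
#' division supplies the validation split that the trainer uses for its
#' own model selection; the trained model is then scored (F1) on the held
#' out fold. The setting with the best mean fold F1 wins; ties go to the
#' first row in grid order.
#'
#' @param X Numeric feature matrix.
#' @param labels 0/1 vector.
#' @param grid data.frame, one row per hyperparameter setting.
#' @param trainer `function(X, labels, params, seed, validation)` returning
#'   a model whose predictions come from [predict_probability()] on
#'   `model$tree`, where `validation = list(X, labels)`.
#' @param folds Outer folds (default 10).
#' @param inner_fraction Inner training fraction (default 0.9).
#' @param seed Integer seed.
#' @param threshold Classification threshold for fold F1.
#' @return list: `best` (winning grid row), `cv_table` (per-setting mean
#'   and sd of fold F1), `fold_f1` (settings x folds matrix).
#' @export
grid_search_cv <- function(X, labels, grid, trainer, folds = 10,
                           inner_fraction = 0.9, seed = 1, threshold = 0.5) {
  if (inherits(X, "feature_matrix")) { labels <- X$y; X <- X$X }
  if (!nrow(grid)) stop("empty hyperparameter grid")
  fold_id <- stratified_folds(labels, folds, substream_seed(seed, "folds"))
  fold_f1 <- matrix(NA_real_, nrow = nrow(grid), ncol = folds)
  for (g in seq_len(nrow(grid))) {
    params <- as.list(grid[g, , drop = FALSE])
    for (f in seq_len(folds)) {
      outer_train <- which(fold_id != f)
      div <- inner_division(labels, outer_train, inner_fraction,
                            substream_seed(seed, sprintf("inner_%d_%d", g, f)))
      model <- trainer(X[div$train, , drop = FALSE], labels[div$train],
                       params, substream_seed(seed, sprintf("train_%d_%d", g, f)),
                       validation = list(X = X[div$val, , drop = FALSE],
                                         labels = labels[div$val]))
      held <- which(fold_id == f)
      p <- predict_probability(model$tree, X[held, , drop = FALSE])
      cts <- confusion(labels[held], p, threshold)
      pan <- metric_panel(cts)
      fold_f1[g, f] <- if (is.na(pan$f1)) 0 else pan$f1
    }
  }
  means <- rowMeans(fold_f1)
  cv_table <- cbind(grid, data.frame(mean_f1 = means,
                                     sd_f1 = apply(fold_f1, 1, stats::sd)))
  best <- which.max(means)   # ties: first in grid order
  list(best = grid[best, , drop = FALSE], cv_table = cv_table,
       fold_f1 = fold_f1)
}

#' Default trainer wrapping the symbolic-regression engine
#'
#' Builds a `trainer` for [grid_search_cv()]: grid parameters override the
#' base evolution parameters, the engine runs on the inner training split,
#' and the final model is selected on the inner validation split.
#'
#' @param base_params [evolution_params()] defaults for parameters not in
#'   the grid.
#' @return A trainer function.
#' @export
gp_trainer <- function(base_params = evolution_params()) {
  function(X, labels, params, seed, validation) {
    p <- unclass(base_params)
    for (nm in names(params)) p[[nm]] <- params[[nm]]
    p$seed <- seed
    fit <- evolve(X, labels, do.call(evolution_params, p))
    sel <- select_final_model(fit$front, validation$X, validation$labels,
                              threshold = p$threshold)
    sel$individual
  }
}

#' Repeated evaluation on random test subsets
#'
#' Runs `runs` evaluations, each on a stratified `fraction`-sized subset of
#' the test set drawn without replacement from a fresh substream, and
#' averages the metric panel. Undefined (NA) metrics are excluded from the
#' mean, with the exclusion count reported.
#'
#' @param model An expression tree, an individual (list with `$tree`), or a
#'   `function(X)` returning probabilities.
#' @param X Test feature matrix.
#' @param labels 0/1 vector.
#' @param runs Number of runs (default 10).
#' @param fraction Subset fraction (default 0.9).
#' @param seed Integer seed.
#' @param threshold Classification threshold.
#' @return list: `mean`, `sd`, `n_excluded` per metric, and `runs`
#'   (per-run data.frame).
#' @export
repeated_test_eval <- function(model, X, labels, runs = 10, fraction = 0.9,
                               seed = 1, threshold = 0.5) {
  if (inherits(X, "feature_matrix")) { labels <- X$y; X <- X$X }
  if (!length(labels) || length(unique(labels)) < 2)
    stop("test set must be non-empty with both classes")
  predict_fun <- if (is.function(model)) model
    else if (!is.null(model$tree)) function(M) predict_probability(model$tree, M)
    else function(M) predict_probability(model, M)
  metric_names <- c("accuracy", "sensitivity", "specificity", "f1",
                    "ppv", "npv", "auc")
  draw_subset <- function(run_seed) {
    idx <- integer(0)
    for (cls in unique(labels)) {
      cl_idx <- which(labels == cls)
      m <- round(fraction * length(cl_idx))
      if (m > 0)
        idx <- c(idx, with_seed(run_seed + cls, draw_(cl_idx, m)))
    }
    sort(idx)
  }
  per_run <- lapply(seq_len(runs), function(r) {
    run_seed <- substream_seed(seed, paste0("test_run_", r))
    idx <- draw_subset(run_seed)
    if (length(unique(labels[idx])) < 2) {       # resample once, then error
      idx <- draw_subset(run_seed + 104729L)
      if (length(unique(labels[idx])) < 2)
        stop("test subset lost an outcome class; increase fraction")
    }
    p <- predict_fun(X[idx, , drop = FALSE])
    rep_ <- metrics_report(labels[idx], p, threshold)
    as.data.frame(rep_[metric_names])
  })
  tab <- do.call(rbind, per_run)
  tab$run <- seq_len(runs)
  list(mean = vapply(metric_names, function(m) mean(tab[[m]], na.rm = TRUE),
                     numeric(1)),
       sd = vapply(metric_names, function(m) stats::sd(tab[[m]], na.rm = TRUE),
                   numeric(1)),
       n_excluded = vapply(metric_names, function(m) sum(is.na(tab[[m]])),
                           integer(1)),
       runs = tab)
}
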