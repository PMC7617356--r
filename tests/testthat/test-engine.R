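test_that("objectives compute clipped BCE and the F1 complement", {
  X <- cbind(x1 = c(0, 0))
  y <- c(1, 0)
  # raw score 0 -> p 0.5 for both rows
  obj <- objectives(parse_formula("x1"), X, y)
  expect_equal(unname(obj["bce"]), log(2), tolerance = 1e-12)
  # hand evaluation: p = (0.8, 0.2) via logit transform of +/-logit(0.8)
  tree <- parse_formula(sprintf("mul(x2, %.17g)", qlogis(0.8)))
  X2 <- cbind(x2 = c(1, -1))
  obj2 <- objectives(tree, X2, y)
  expect_equal(unname(obj2["bce"]), -log(0.8), tolerance = 1e-10)
  expect_equal(unname(obj2["f1_complement"]), 0)
  expect_error(objectives(parse_formula("x1"), X, c(1, 1)),
               "both outcome classes")
})

test_that("predicted probabilities are the logistic link of raw scores", {
  X <- cbind(x1 = c(0, 20, -20))
  p <- predict_probability(parse_formula("x1"), X)
  expect_equal(p[1], 0.5)
  expect_gt(p[2], 1 - 1e-6)
  expect_lt(p[3], 1e-6)
  # vector evaluation equals per-row scalar calls
  set.seed(3)
  tree <- random_test_tree(c("x1"))
  Xr <- cbind(x1 = rnorm(20))
  scalar <- vapply(seq_len(20), function(i)
    predict_probability(tree, Xr[i, , drop = FALSE]), numeric(1))
  expect_equal(predict_probability(tree, Xr), scalar)
})

test_that("non-dominated sort matches the pairwise-dominance oracle", {
  objs <- rbind(c(1, 1), c(2, 2), c(1, 2), c(2, 1))
  fronts <- non_dominated_sort(objs)
  expect_equal(fronts, list(1L, c(3L, 4L), 2L))
  # duplicated objective vectors share a front
  dup <- rbind(c(1, 1), c(1, 1))
  expect_equal(non_dominated_sort(dup), list(c(1L, 2L)))
  expect_equal(non_dominated_sort(matrix(c(1, 1), 1)), list(1L))
  set.seed(5)
  for (n in c(10, 50, 120, 200)) {
    o <- matrix(sample(1:12, n * 2, replace = TRUE), ncol = 2)
    got <- non_dominated_sort(o)
    want <- oracle_fronts(o)
    expect_equal(lapply(got, sort), lapply(want, sort))
  }
})

test_that("crowding distance follows the standard formula", {
  expect_equal(crowding_distance(rbind(c(1, 1))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 1), c(2, 2))), c(Inf, Inf))
  three <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_equal(crowding_distance(three), c(Inf, 2, Inf))
  flat <- rbind(c(0, 5), c(1, 5), c(2, 5))   # zero range on one axis
  expect_equal(crowding_distance(flat), c(Inf, 1, Inf))
})

test_that("a separable signal is solved quickly and history is monotone", {
  fx <- make_fixture("separable", seed = 2)
  fit <- evolve(fx$X, fx$y,
                evolution_params(population = 50, generations = 30, seed = 1))
  expect_lte(min(fit$history$best_f1c), 1e-12)
  expect_true(all(diff(fit$history$best_bce) <= 1e-12))
  expect_true(all(diff(fit$history$best_f1c) <= 1e-12))
  expect_true(all(vapply(fit$front, function(i) i$rank == 0L, logical(1))))
  # no front member dominates another
  objs <- t(vapply(fit$front, function(i) i$objectives, numeric(2)))
  expect_equal(length(oracle_fronts(objs)), 1L)
})

test_that("zero generations returns the evaluated initial population", {
  fx <- make_fixture("separable", seed = 4)
  fit <- evolve(fx$X, fx$y,
                evolution_params(population = 20, generations = 0, seed = 9))
  expect_equal(nrow(fit$history), 0L)
  expect_gt(length(fit$front), 0L)
})

test_that("evolution is deterministic under a fixed seed", {
  fx <- make_fixture("separable", seed = 6)
  p <- evolution_params(population = 30, generations = 8, seed = 123)
  f1 <- evolve(fx$X, fx$y, p)
  f2 <- evolve(fx$X, fx$y, p)
  expect_identical(vapply(f1$front, function(i) serialize_formula(i$tree),
                          character(1)),
                   vapply(f2$front, function(i) serialize_formula(i$tree),
                          character(1)))
  expect_identical(f1$history, f2$history)
})

test_that("final model selection ranks by AUC, then sensitivity, then size", {
  mk <- function(formula) {
    tree <- parse_formula(formula)
    list(tree = tree, objectives = c(bce = 0, f1_complement = 0),
         nodes = tree_size(tree))
  }
  # x1 separates the labels perfectly; x2 is noise
  X <- cbind(x1 = c(3, 2, -2, -3), x2 = c(1, -1, 1, -1))
  y <- c(1, 1, 0, 0)
  sel <- select_final_model(list(mk("x2"), mk("x1")), X, y)
  expect_equal(serialize_formula(sel$individual$tree), "x1")
  expect_equal(
    serialize_formula(select_final_model(list(mk("x1")), X, y)$individual$tree),
    "x1")
  # identical predictions -> full metric tie -> smaller tree wins
  sel2 <- select_final_model(list(mk("add(x1, 0)"), mk("x1")), X, y)
  expect_equal(serialize_formula(sel2$individual$tree), "x1")
})

test_that("model files round-trip formula and metadata", {
  path <- tempfile(fileext = ".model")
  ind <- list(tree = parse_formula("add(x1, mul(2, x2))"),
              objectives = c(bce = 0.5, f1_complement = 0.25), nodes = 5L)
  write_model(ind, path, evolution_params(seed = 77))
  back <- read_model(path)
  expect_equal(serialize_formula(back$tree), "add(x1, mul(2, x2))")
  expect_equal(back$meta$seed, 77)
  expect_equal(back$meta$objectives$bce, 0.5)
})

test_that("the F1 objective improves recall over a BCE-only run on
           imbalanced data", {
  wins <- 0L
  for (seed in 1:3) {
    n <- 600
    X <- with_seed(seed, cbind(x1 = rnorm(n, 0, 2), x2 = rnorm(n)))
    p <- plogis(3 * X[, "x1"] - 5.4)       # prevalence around 6%
    y <- with_seed(seed + 100, rbinom(n, 1, p))
    if (sum(y) < 8) next
    sp <- stratified_split(data.frame(death_1y = y), fraction = 0.8,
                           seed = seed)
    tr <- sp$train_idx; te <- sp$test_idx
    recall_of <- function(objective) {
      fit <- evolve(X[tr, ], y[tr],
                    evolution_params(population = 40, generations = 20,
                                     objective = objective, seed = seed))
      best <- which.min(vapply(fit$front, function(i)
        if (objective == "bce") i$objectives[1] else i$objectives[2],
        numeric(1)))
      pr <- predict_probability(fit$front[[best]]$tree, X[te, ])
      pan <- metric_panel(confusion(y[te], pr))
      if (is.na(pan$sensitivity)) 0 else pan$sensitivity
    }
    if (recall_of("multi") > recall_of("bce")) wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})
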