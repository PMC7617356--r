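test_that("additivity forces the attributions of an additive model", {
  tree <- parse_formula("add(x1, mul(2, x2))")
  background <- cbind(x1 = 0, x2 = 0)
  res <- shapley_exact(tree, list(x1 = 1, x2 = 1), background, scale = "raw")
  expect_equal(unname(res$attributions), c(1, 2))
  expect_equal(res$base_value, 0)
  expect_equal(res$base_value + sum(res$attributions), res$full_value)
})

test_that("exact enumeration matches the all-permutations oracle on an
           interaction model", {
  tree <- parse_formula("add(mul(x1, x2), x3)")
  set.seed(5)
  background <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
  row <- list(x1 = 1.5, x2 = -0.5, x3 = 2)
  res <- shapley_exact(tree, row, background, scale = "raw")
  f <- function(M) eval_tree(tree, M)
  want <- oracle_shapley_perms(f, row, background, paste0("x", 1:3))
  expect_equal(res$attributions, want, tolerance = 1e-10)
  expect_equal(res$base_value + sum(res$attributions), res$full_value,
               tolerance = 1e-10)
})

test_that("null players get exactly zero and symmetric players equal shares", {
  # x3 never appears in the formula
  tree <- parse_formula("add(x1, x2)")
  set.seed(6)
  background <- matrix(rnorm(24), 8, 3, dimnames = list(NULL, paste0("x", 1:3)))
  res <- shapley_exact(tree, list(x1 = 1, x2 = 2, x3 = 99), background,
                       scale = "raw")
  expect_equal(unname(res$attributions["x3"]), 0)
  # symmetric use + identical values + exchangeable background -> equal shares
  bg_sym <- background
  bg_sym[, "x2"] <- bg_sym[, "x1"]
  res_sym <- shapley_exact(tree, list(x1 = 3, x2 = 3, x3 = 0), bg_sym,
                           scale = "raw")
  expect_equal(unname(res_sym$attributions["x1"]),
               unname(res_sym$attributions["x2"]), tolerance = 1e-12)
})

test_that("feature count above 12 is routed to the sampling estimator", {
  nms <- paste0("x", 1:13)
  background <- matrix(0, 2, 13, dimnames = list(NULL, nms))
  expect_error(shapley_exact(parse_formula("x1"),
                             as.list(setNames(rep(1, 13), nms)), background),
               "shapley_sampled")
})

test_that("the sampling estimator agrees with enumeration within 3 SE", {
  tree <- parse_formula("add(mul(x1, x2), sub(exp(x3), mul(x4, x5)))")
  set.seed(8)
  nms <- paste0("x", 1:5)
  background <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, nms))
  row <- as.list(setNames(rnorm(5), nms))
  exact <- shapley_exact(tree, row, background, scale = "raw")
  samp <- shapley_sampled(tree, row, background, n_permutations = 2000,
                          seed = 42, scale = "raw")
  for (nm in nms) {
    tol <- max(3 * samp$se[nm], 1e-9)
    expect_lt(abs(samp$attributions[nm] - exact$attributions[nm]), tol)
  }
  # telescoping construction keeps the sum exactly additive
  expect_equal(samp$base_value + sum(samp$attributions), samp$full_value,
               tolerance = 1e-10)
})

test_that("doubling permutations roughly halves the estimator variance", {
  tree <- parse_formula("add(mul(x1, x2), x3)")
  set.seed(10)
  nms <- paste0("x", 1:3)
  background <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, nms))
  row <- list(x1 = 2, x2 = -1, x3 = 0.5)
  est <- function(P, seeds) vapply(seeds, function(s)
    shapley_sampled(tree, row, background, n_permutations = P, seed = s,
                    scale = "raw")$attributions["x1"], numeric(1))
  v1 <- var(est(8, 1:150))
  v2 <- var(est(16, 201:350))
  expect_gt(v2 / v1, 0.3)
  expect_lt(v2 / v1, 0.7)
})

test_that("a constant model attributes nothing, with zero SE", {
  tree <- parse_formula("3.5")
  background <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("x1", "x2")))
  res <- shapley_sampled(tree, list(x1 = 1, x2 = 2), background,
                         n_permutations = 50, seed = 1, scale = "raw")
  expect_true(all(res$attributions == 0))
  expect_true(all(res$se == 0))
})

test_that("importance summaries rank planted effect sizes correctly", {
  # coefficients 3 vs 0.3: the former must dominate mean |attribution|
  tree <- parse_formula("add(mul(3, x1), mul(0.3, x2))")
  set.seed(12)
  nms <- c("x1", "x2")
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, nms))
  background <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, nms))
  rep_ <- shap_report(tree, X, background, scale = "raw")
  imp <- summarize_importance(rep_)
  expect_equal(imp$feature[1], "x1")
  expect_gt(imp$mean_abs_attribution[1], imp$mean_abs_attribution[2])
  expect_gt(imp$direction[1], 0)
  # single patient: ranking by that patient's absolute attributions
  rep1 <- shap_report(tree, X[1, , drop = FALSE], background, scale = "raw")
  imp1 <- summarize_importance(rep1)
  expect_equal(imp1$mean_abs_attribution,
               sort(abs(rep1$attributions[1, ]), decreasing = TRUE),
               ignore_attr = TRUE)
})

test_that("report-level additivity holds for every explained patient", {
  tree <- parse_formula("add(mul(x1, x2), sqrt(x3))")
  set.seed(14)
  nms <- paste0("x", 1:4)           # x4 is a null player
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, nms))
  background <- matrix(rnorm(32), 8, 4, dimnames = list(NULL, nms))
  rep_ <- shap_report(tree, X, background, scale = "probability")
  p <- predict_probability(tree, X)
  got <- rep_$base_value + rowSums(rep_$attributions)
  # base over the full background vs mean over pinned coalitions coincide
  expect_equal(got, p, tolerance = 1e-8)
  expect_true(all(rep_$attributions[, "x4"] == 0))
  # beeswarm export carries one row per patient-feature pair
  pd <- shap_plot_data(rep_)
  expect_equal(nrow(pd), 40L)
})
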