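# Model-agnostic Shapley-value feature attribution with the marginal
# (interventional) expectation: absent features take background-row values.
# Exact enumeration up to 12 features; permutation sampling beyond.

# model -> function(matrix) -> numeric output
as_model_fun <- function(model, scale = c("probability", "raw")) {
  scale <- match.arg(scale)
  if (is.function(model)) return(model)
  tree <- if (!is.null(model$tree)) model$tree else model
  if (scale == "probability") function(M) predict_probability(tree, M)
  else function(M) eval_tree(tree, M)
}

row_as_list <- function(row) {
  if (is.numeric(row) && !is.null(names(row))) return(as.list(row))
  as.list(as.data.frame(row, stringsAsFactors = FALSE))
}

# coalition value: mean model output over background rows with coalition
# features pinned to the explained row's values
coalition_value <- function(f, row, background, members) {
  M <- background
  for (nm in members) M[, nm] <- row[[nm]]
  mean(f(M))
}

#' Exact Shapley attributions by coalition enumeration
#'
#' Classic Shapley values with value function v(S) = mean model output when
#' the features in S take the explained row's values and the rest are drawn
#' from the background rows. Exactly additive: base value plus the
#' attribution sum equals v(all features).
#'
#' @param model Expression tree, individual, or `function(matrix)`.
#' @param row Named list / one-row data.frame with the explained values.
#' @param background Matrix of background rows (named columns).
#' @param features Features to attribute over (default: all background
#'   columns); at most 12 (2^k enumeration) — beyond that use
#'   [shapley_sampled()].
#' @param scale `"probability"` (post-logistic, default) or `"raw"`.
#' @return list: `attributions` (named vector), `base_value`, `full_value`,
#'   `scale`.
#' @export
shapley_exact <- function(model, row, background, features = NULL,
                          scale = c("probability", "raw")) {
  f <- as_model_fun(model, scale)
  if (is.null(features)) features <- colnames(background)
  k <- length(features)
  if (k > 12)
    stop("more than 12 features: use shapley_sampled() for estimation")
  row <- row_as_list(row)
  v <- numeric(2^k)
  nb <- nrow(background)
  bits <- bitwShiftL(1L, seq_len(k) - 1L)
  chunk <- max(1L, as.integer(floor(20000 / nb)))
  masks <- 0:(2^k - 1)
  for (grp in split(masks, ceiling(seq_along(masks) / chunk))) {
    mats <- lapply(grp, function(mask) {
      M <- background
      for (nm in features[bitwAnd(mask, bits) != 0L]) M[, nm] <- row[[nm]]
      M
    })
    v[grp + 1L] <- colMeans(matrix(f(do.call(rbind, mats)), nrow = nb))
  }
  fact <- factorial(0:max(k, 1))
  phi <- stats::setNames(numeric(k), features)
  for (i in seq_len(k)) {
    bit <- bitwShiftL(1L, i - 1L)
    for (mask in 0:(2^k - 1)) {
      if (bitwAnd(mask, bit) != 0L) next
      s <- sum(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
      w <- fact[s + 1] * fact[k - s] / fact[k + 1]
      phi[i] <- phi[i] + w * (v[bitwOr(mask, bit) + 1L] - v[mask + 1L])
    }
  }
  list(attributions = phi, base_value = v[1], full_value = v[2^k],
       scale = match.arg(scale))
}

#' Permutation-sampling Shapley estimator
#'
#' Unbiased Monte-Carlo estimate of the exact Shapley values: for each
#' sampled feature permutation the marginal contributions telescope from
#' v(empty) to v(all features), so the attribution sum is exactly additive
#' by construction; only the per-feature split carries Monte-Carlo error,
#' reported as a standard error.
#'
#' @inheritParams shapley_exact
#' @param n_permutations Number of permutations (>= 1).
#' @param seed Integer seed.
#' @return list: `attributions`, `se` (per-feature Monte-Carlo SE),
#'   `base_value`, `full_value`, `scale`.
#' @export
shapley_sampled <- function(model, row, background, n_permutations = 200,
                            seed = 1, features = NULL,
                            scale = c("probability", "raw")) {
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  f <- as_model_fun(model, scale)
  if (is.null(features)) features <- colnames(background)
  k <- length(features)
  row <- row_as_list(row)
  base <- coalition_value(f, row, background, character(0))
  full <- coalition_value(f, row, background, features)
  contribs <- matrix(0, nrow = n_permutations, ncol = k,
                     dimnames = list(NULL, features))
  perms <- with_seed(seed, lapply(seq_len(n_permutations),
                                  function(i) shuffle_(features)))
  # batched evaluation: stack every prefix coalition of a chunk of
  # permutations into one matrix and call the model once
  nb <- nrow(background)
  chunk <- max(1L, min(n_permutations,
                       as.integer(floor(20000 / max(1, k * nb)))))
  p0 <- 1L
  while (p0 <= n_permutations) {
    p1 <- min(p0 + chunk - 1L, n_permutations)
    mats <- vector("list", (p1 - p0 + 1L) * k)
    m <- 0L
    for (p in p0:p1) {
      ord <- perms[[p]]
      M <- background
      for (j in seq_len(k)) {
        M[, ord[j]] <- row[[ord[j]]]
        m <- m + 1L
        mats[[m]] <- M
      }
    }
    v <- colMeans(matrix(f(do.call(rbind, mats)), nrow = nb))
    i <- 0L
    for (p in p0:p1) {
      ord <- perms[[p]]
      prev <- base
      for (j in seq_len(k)) {
        i <- i + 1L
        val <- if (j == k) full else v[i]
        contribs[p, ord[j]] <- val - prev
        prev <- val
      }
    }
    p0 <- p1 + 1L
  }
  phi <- colMeans(contribs)
  se <- if (n_permutations > 1) apply(contribs, 2, stats::sd) / sqrt(n_permutations)
        else rep(NA_real_, k)
  list(attributions = phi, se = stats::setNames(se, features),
       base_value = base, full_value = full, scale = match.arg(scale))
}

#' Shapley report for a set of patients
#'
#' Computes per-patient attributions over every column of `X`. Features the
#' model's formula never references are null players with exactly zero
#' attribution, so enumeration/sampling is restricted to the referenced
#' features: exact when they number at most 12, permutation sampling
#' otherwise.
#'
#' @param model Expression tree or individual (list with `$tree`).
#' @param X Matrix of patients to explain (named columns).
#' @param background Background matrix (same columns).
#' @param n_permutations Permutations for the sampled path.
#' @param seed Integer seed.
#' @param scale `"probability"` or `"raw"`.
#' @return list of class `shap_report`: `attributions` (patients x
#'   features), `values` (the explained feature values), `base_value`,
#'   `scale`.
#' @export
shap_report <- function(model, X, background, n_permutations = 200,
                        seed = 1, scale = c("probability", "raw")) {
  scale <- match.arg(scale)
  if (inherits(X, "feature_matrix")) X <- X$X
  if (inherits(background, "feature_matrix")) background <- background$X
  tree <- if (!is.null(model$tree)) model$tree else model
  used <- intersect(tree_features(tree), colnames(X))
  A <- matrix(0, nrow = nrow(X), ncol = ncol(X),
              dimnames = list(NULL, colnames(X)))
  base <- mean(as_model_fun(tree, scale)(background))
  if (length(used)) {
    for (r in seq_len(nrow(X))) {
      row <- as.list(as.data.frame(X[r, , drop = FALSE]))
      res <- if (length(used) <= 12)
        shapley_exact(tree, row, background, features = used, scale = scale)
      else shapley_sampled(tree, row, background,
                           n_permutations = n_permutations,
                           seed = substream_seed(seed, paste0("patient_", r)),
                           features = used, scale = scale)
      A[r, used] <- res$attributions[used]
    }
  }
  structure(list(attributions = A, values = X, base_value = base,
                 scale = scale), class = "shap_report")
}

#' Rank features by attribution magnitude, with effect directions
#'
#' Features are ranked by mean absolute attribution across patients; the
#' direction summary is the Pearson correlation between each feature's
#' attribution and its value (positive: higher values push risk up).
#'
#' @param report A `shap_report` (or list of per-patient reports sharing
#'   feature names).
#' @return data.frame: `feature`, `mean_abs_attribution`, `direction`
#'   (correlation, NA when degenerate), ranked.
#' @export
summarize_importance <- function(report) {
  if (!inherits(report, "shap_report")) {
    A <- do.call(rbind, lapply(report, function(r) r$attributions))
    V <- do.call(rbind, lapply(report, function(r) unlist(r$values)))
  } else {
    A <- report$attributions
    V <- report$values
  }
  if (!nrow(A)) stop("need at least one patient report")
  dir_cor <- function(a, v) {
    if (length(a) < 2) return(NA_real_)
    sa <- stats::sd(a); sv <- stats::sd(v)
    if (is.na(sa) || is.na(sv) || sa == 0 || sv == 0) return(NA_real_)
    stats::cor(a, v)
  }
  out <- data.frame(
    feature = colnames(A),
    mean_abs_attribution = colMeans(abs(A)),
    direction = vapply(seq_len(ncol(A)),
                       function(j) dir_cor(A[, j], V[, j]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$mean_abs_attribution, out$feature), , drop = FALSE]
}

#' Export beeswarm-style plot data
#'
#' One row per (patient, feature): feature value and attribution, the raw
#' material of a SHAP summary plot.
#'
#' @param report A `shap_report`.
#' @param path Optional CSV path; when given, written and returned
#'   invisibly.
#' @return data.frame `feature`, `value`, `attribution`.
#' @export
shap_plot_data <- function(report, path = NULL) {
  A <- report$attributions; V <- report$values
  out <- do.call(rbind, lapply(seq_len(ncol(A)), function(j) {
    data.frame(feature = colnames(A)[j], value = V[, j],
               attribution = A[, j], stringsAsFactors = FALSE)
  }))
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
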