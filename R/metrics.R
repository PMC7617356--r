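# Classification metric panel, ROC AUC (Mann-Whitney form), calibration
# bins, and the train-vs-test consistency gap.

#' Confusion counts at a threshold
#'
#' Prediction is positive iff `probability >= threshold`.
#'
#' @param labels 0/1 vector.
#' @param probabilities Numeric vector, same length.
#' @param threshold Decision threshold (default 0.5).
#' @return list(TP, FP, TN, FN).
#' @export
confusion <- function(labels, probabilities, threshold = 0.5) {
  if (length(labels) != length(probabilities))
    stop("labels and probabilities differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  pred <- as.integer(probabilities >= threshold)
  list(TP = sum(pred == 1 & labels == 1),
       FP = sum(pred == 1 & labels == 0),
       TN = sum(pred == 0 & labels == 0),
       FN = sum(pred == 0 & labels == 1))
}

#' Scalar classification metrics from confusion counts
#'
#' Any 0/0 ratio is reported as `NA` (an explicit undefined marker) rather
#' than a silent 0, with one exception following the standard F1
#' convention: F1 is 0 when TP = 0 but FP + FN > 0.
#'
#' @param counts list(TP, FP, TN, FN) from [confusion()].
#' @return Named list: accuracy, sensitivity, specificity, f1, ppv, npv.
#' @export
metric_panel <- function(counts) {
  with(counts, {
    total <- TP + FP + TN + FN
    if (total == 0) stop("no evaluated patients")
    ratio <- function(num, den) if (den == 0) NA_real_ else num / den
    f1 <- if (2 * TP + FP + FN == 0) NA_real_ else 2 * TP / (2 * TP + FP + FN)
    list(accuracy = (TP + TN) / total,
         sensitivity = ratio(TP, TP + FN),
         specificity = ratio(TN, TN + FP),
         f1 = f1,
         ppv = ratio(TP, TP + FP),
         npv = ratio(TN, TN + FN))
  })
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a random positive case
#' outscores a random negative one, ties counting one half.
#'
#' @param labels 0/1 vector with both classes present.
#' @param probabilities Scores (any monotone scale).
#' @return AUC in [0, 1], or `NA` if only one class is present.
#' @export
roc_auc <- function(labels, probabilities) {
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(probabilities, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Calibration bins
#'
#' Equal-width probability bins on [0, 1]; every bin is left-open
#' right-closed except the first, which includes 0.
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities in [0, 1].
#' @param n_bins Number of bins (>= 2, default 10).
#' @return data.frame: `bin_low`, `bin_high`, `mean_predicted`,
#'   `observed_rate`, `count`, `empty` flag.
#' @export
calibration_bins <- function(labels, probabilities, n_bins = 10) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  edges <- seq(0, 1, length.out = n_bins + 1)
  idx <- findInterval(probabilities, edges, left.open = TRUE, all.inside = TRUE)
  out <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                    mean_predicted = NA_real_, observed_rate = NA_real_,
                    count = 0L, empty = TRUE)
  for (b in seq_len(n_bins)) {
    in_bin <- idx == b
    if (any(in_bin)) {
      out$mean_predicted[b] <- mean(probabilities[in_bin])
      out$observed_rate[b] <- mean(labels[in_bin])
      out$count[b] <- sum(in_bin)
      out$empty[b] <- FALSE
    }
  }
  out
}

#' Full metrics report for one evaluation
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities.
#' @param threshold Decision threshold.
#' @param n_bins Calibration bins.
#' @return list: `counts`, scalar metrics (as [metric_panel()]), `auc`,
#'   `calibration`.
#' @export
metrics_report <- function(labels, probabilities, threshold = 0.5,
                           n_bins = 10) {
  counts <- confusion(labels, probabilities, threshold)
  c(metric_panel(counts),
    list(auc = roc_auc(labels, probabilities),
         counts = counts,
         calibration = calibration_bins(labels, probabilities, n_bins)))
}

#' Train-vs-test consistency gap
#'
#' @param train_report,test_report Reports sharing scalar metric names.
#' @param metrics Which metrics to difference.
#' @return Named numeric vector of train minus test values.
#' @export
overfit_gap <- function(train_report, test_report,
                        metrics = c("accuracy", "sensitivity", "specificity",
                                    "f1", "ppv", "npv", "auc")) {
  vapply(metrics, function(m) {
    a <- train_report[[m]]; b <- test_report[[m]]
    if (is.null(a) || is.null(b)) stop("metric missing from a report: ", m)
    as.numeric(a) - as.numeric(b)
  }, numeric(1))
}
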