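# Synthetic perioperative cohort generator: independent (or Gaussian-copula
# paired) marginals plus a logistic-additive planted outcome mechanism.

#' Build a generator configuration
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Master seed for the generator.
#' @param baseline_logit Intercept of the logistic outcome mechanism. The
#'   default is calibrated by large-sample Monte Carlo so that, with the
#'   default effects, expected 1-year mortality prevalence is 5.5%.
#' @param effects Effect table: columns `feature`, `transform`
#'   (`linear` | `threshold_above` | `threshold_below`), `threshold`, `coef`.
#' @param marginals Marginal-distribution table (see [default_marginals()]).
#' @param missing_rate MCAR cell-missingness proportion in [0, 1); outcome
#'   and id are never made missing.
#' @param correlations Rank-correlation pairs among continuous features,
#'   induced by a Gaussian copula: data.frame with columns `f1`, `f2`, `rho`.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_patients = 1190,
                             seed = 1,
                             baseline_logit = -2.82635,
                             effects = default_effects(),
                             marginals = default_marginals(),
                             missing_rate = 0,
                             correlations = data.frame(
                               f1 = "peak_vo2", f2 = "at_vo2", rho = 0.7,
                               stringsAsFactors = FALSE)) {
  cfg <- structure(
    list(n_patients = n_patients, seed = seed, baseline_logit = baseline_logit,
         effects = effects, marginals = marginals, missing_rate = missing_rate,
         correlations = correlations),
    class = "generator_config")
  validate_generator_config(cfg)
  cfg
}

#' @keywords internal
validate_generator_config <- function(cfg) {
  m <- cfg$marginals
  if (cfg$n_patients < 0) stop("n_patients must be non-negative")
  if (!(cfg$missing_rate >= 0 && cfg$missing_rate < 1))
    stop("missing_rate must be in [0, 1)")
  for (i in seq_len(nrow(m))) {
    f <- m$feature[i]
    if (m$class[i] == "continuous") {
      if (!is.finite(m$low[i]) || !is.finite(m$high[i]) || m$low[i] >= m$high[i])
        stop(sprintf("feature '%s': truncation bounds must be finite with low < high", f))
      if (!is.finite(m$sd[i]) || m$sd[i] <= 0)
        stop(sprintf("feature '%s': sd must be positive", f))
    } else if (m$class[i] == "binary") {
      if (is.na(m$p[i]) || m$p[i] < 0 || m$p[i] > 1)
        stop(sprintf("feature '%s': Bernoulli probability must lie in [0,1]", f))
    } else if (m$class[i] == "categorical") {
      pr <- as.numeric(strsplit(m$probs[i], ",")[[1]])
      if (any(pr < 0) || abs(sum(pr) - 1) > 1e-6)
        stop(sprintf("feature '%s': category probabilities must be non-negative and sum to 1", f))
      lv <- strsplit(m$levels[i], ",")[[1]]
      if (length(lv) != length(pr))
        stop(sprintf("feature '%s': levels and probabilities differ in length", f))
    } else stop(sprintf("feature '%s': unknown class '%s'", f, m$class[i]))
  }
  bad <- setdiff(cfg$effects$feature, m$feature)
  if (length(bad))
    stop("effect features not in marginal table: ", paste(bad, collapse = ", "))
  if (!all(cfg$effects$transform %in% c("linear", "threshold_above", "threshold_below")))
    stop("unknown effect transform")
  if (nrow(cfg$correlations)) {
    if (any(abs(cfg$correlations$rho) >= 1)) stop("copula rho must be in (-1, 1)")
    cf <- unique(c(cfg$correlations$f1, cfg$correlations$f2))
    if (!all(cf %in% m$feature[m$class == "continuous"]))
      stop("correlation pairs must name continuous features")
  }
  invisible(cfg)
}

# inverse-CDF truncated normal: u in (0,1) -> value
qtruncnorm_ <- function(u, mean, sd, low, high) {
  plo <- stats::pnorm((low - mean) / sd)
  phi <- stats::pnorm((high - mean) / sd)
  mean + sd * stats::qnorm(plo + u * (phi - plo))
}

#' Sample feature values (no outcome) for n patients
#' @keywords internal
sample_features <- function(cfg, n, seed) {
  m <- cfg$marginals
  nf <- nrow(m)
  z <- with_seed(seed, matrix(stats::rnorm(n * nf), nrow = n, ncol = nf))
  colnames(z) <- m$feature
  # Gaussian copula on declared pairs: rebuild the second member from the first
  if (nrow(cfg$correlations)) {
    for (i in seq_len(nrow(cfg$correlations))) {
      a <- cfg$correlations$f1[i]; b <- cfg$correlations$f2[i]
      rho <- cfg$correlations$rho[i]
      z[, b] <- rho * z[, a] + sqrt(1 - rho^2) * z[, b]
    }
  }
  u <- stats::pnorm(z)
  out <- vector("list", nf)
  names(out) <- m$feature
  for (i in seq_len(nf)) {
    f <- m$feature[i]
    if (m$class[i] == "continuous") {
      out[[f]] <- qtruncnorm_(u[, f], m$mean[i], m$sd[i], m$low[i], m$high[i])
    } else if (m$class[i] == "binary") {
      out[[f]] <- as.integer(u[, f] < m$p[i])
    } else {
      lv <- strsplit(m$levels[i], ",")[[1]]
      pr <- as.numeric(strsplit(m$probs[i], ",")[[1]])
      pr <- pr / sum(pr)
      out[[f]] <- lv[findInterval(u[, f], cumsum(pr), left.open = TRUE) + 1L]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# linear predictor of the planted mechanism (excluding the intercept)
effect_eta <- function(data, effects) {
  eta <- numeric(nrow(data))
  for (i in seq_len(nrow(effects))) {
    f <- effects$feature[i]
    if (!f %in% names(data)) stop("missing required feature: ", f)
    x <- data[[f]]
    if (any(is.na(x))) stop("missing value in required feature: ", f)
    eta <- eta + switch(effects$transform[i],
      linear = effects$coef[i] * (x - effects$threshold[i]),
      threshold_above = effects$coef[i] * as.numeric(x > effects$threshold[i]),
      threshold_below = effects$coef[i] * as.numeric(x < effects$threshold[i]))
  }
  eta
}

#' Planted outcome probability for one patient record
#'
#' Evaluates the logistic-additive mechanism
#' `plogis(baseline_logit + sum_i coef_i * transform_i(x_i))`.
#'
#' @param record A named list or one-row data.frame holding (at least) every
#'   feature named in the config's effect table, non-missing.
#' @param config A [generator_config()].
#' @return Probability in (0, 1).
#' @export
outcome_probability <- function(record, config) {
  if (!nrow(config$effects))
    return(stats::plogis(config$baseline_logit))
  df <- as.data.frame(record, stringsAsFactors = FALSE)
  stats::plogis(config$baseline_logit + effect_eta(df, config$effects))
}

#' Sample a synthetic cohort
#'
#' Draws `n_patients` feature vectors from the configured marginals (with
#' Gaussian-copula correlation on declared pairs), then draws the binary
#' 1-year mortality outcome from the planted logistic mechanism, and
#' optionally injects MCAR missingness into feature cells.
#'
#' @param config A [generator_config()].
#' @return A data.frame: `patient_id`, all schema features, `death_1y`.
#' @export
sample_cohort <- function(config) {
  validate_generator_config(config)
  n <- config$n_patients
  if (n == 0) {
    feats <- sample_features(config, 1, substream_seed(config$seed, "marginals"))[0, , drop = FALSE]
    return(cbind(data.frame(patient_id = character(0), stringsAsFactors = FALSE),
                 feats, data.frame(death_1y = integer(0))))
  }
  feats <- sample_features(config, n, substream_seed(config$seed, "marginals"))
  p <- stats::plogis(config$baseline_logit + effect_eta(feats, config$effects))
  y <- with_seed(substream_seed(config$seed, "outcome"),
                 stats::rbinom(n, 1L, p))
  tab <- cbind(data.frame(patient_id = sprintf("P%05d", seq_len(n)),
                          stringsAsFactors = FALSE),
               feats, data.frame(death_1y = y))
  if (config$missing_rate > 0)
    tab <- inject_missingness(tab, config$missing_rate,
                              substream_seed(config$seed, "missing"))
  tab
}

#' Inject missing-completely-at-random cells
#'
#' Each feature cell is independently set to `NA` with probability `rate`;
#' the outcome (`death_1y`) and `patient_id` columns are never touched.
#'
#' @param table A cohort data.frame.
#' @param rate Proportion in [0, 1).
#' @param seed Integer seed; identical seeds give identical masks.
#' @return The table with missing cells.
#' @export
inject_missingness <- function(table, rate, seed) {
  if (!(rate >= 0 && rate < 1)) stop("rate must be in [0, 1)")
  if (rate == 0) return(table)
  cols <- setdiff(names(table), c("patient_id", "death_1y"))
  mask <- with_seed(seed,
    matrix(stats::runif(nrow(table) * length(cols)) < rate,
           nrow = nrow(table)))
  for (j in seq_along(cols)) table[[cols[j]]][mask[, j]] <- NA
  table
}

#' Calibrate the baseline logit to a target prevalence
#'
#' Solves `mean(plogis(b + eta)) = target` over a large Monte-Carlo feature
#' sample, where `eta` is the planted effect linear predictor.
#'
#' @param config A [generator_config()]; its `baseline_logit` is ignored.
#' @param target Target outcome prevalence (default 0.055).
#' @param n Monte-Carlo sample size.
#' @param seed Seed for the Monte-Carlo draw.
#' @return The calibrated baseline logit (numeric scalar).
#' @export
calibrate_baseline_logit <- function(config, target = 0.055,
                                     n = 400000, seed = 760731) {
  feats <- sample_features(config, n, seed)
  eta <- effect_eta(feats, config$effects)
  f <- function(b) mean(stats::plogis(b + eta)) - target
  stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
}

#' Write a cohort to CSV
#'
#' UTF-8, "." decimal separator, header row, missing cells as empty fields.
#'
#' @param table Cohort data.frame.
#' @param path Output path.
#' @export
write_cohort <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort from CSV, validating the schema
#'
#' Validates that the outcome column `death_1y` is present, binary and never
#' missing, and that every categorical value belongs to its declared level
#' set; violations are reported with their location.
#'
#' @param path CSV path written by [write_cohort()].
#' @param schema Feature schema (default [cohort_schema()]).
#' @return A cohort data.frame.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8")
  if (!"death_1y" %in% names(tab))
    stop("malformed cohort file: no 'death_1y' outcome column")
  if (anyNA(tab$death_1y)) {
    row <- which(is.na(tab$death_1y))[1]
    stop(sprintf("missing outcome value at row %d, column 'death_1y'", row))
  }
  if (!all(tab$death_1y %in% c(0L, 1L)))
    stop("outcome column 'death_1y' must be binary 0/1")
  for (i in which(schema$class == "categorical")) {
    f <- schema$feature[i]
    if (!f %in% names(tab)) next
    lv <- strsplit(schema$levels[i], ",")[[1]]
    vals <- tab[[f]]
    bad <- which(!is.na(vals) & !(vals %in% lv))
    if (length(bad))
      stop(sprintf("unknown category label '%s' at row %d, column '%s'",
                   vals[bad[1]], bad[1], f))
  }
  tab
}
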