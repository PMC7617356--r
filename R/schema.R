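# Cohort schema: 39 clinical + 46 cardiorespiratory-fitness features, one
# binary outcome (death_1y). Continuous marginals are truncated normals
# chosen to match published medians/IQRs/ranges where available and
# clinically plausible values elsewhere; binaries are Bernoulli with the
# published cohort proportions.

#' Cohort feature schema
#'
#' Describes every feature of the synthetic perioperative cohort: name,
#' measurement class (`continuous`, `binary`, `categorical`), feature group
#' (`clinical` or `fitness`) and, for categoricals, the declared level set.
#'
#' @return A data.frame with columns `feature`, `class`, `group`, `levels`
#'   (comma-separated for categoricals, `NA` otherwise). 39 clinical and
#'   46 fitness rows.
#' @export
cohort_schema <- function() {
  m <- default_marginals()
  data.frame(
    feature = m$feature,
    class = m$class,
    group = m$group,
    levels = m$levels,
    stringsAsFactors = FALSE
  )
}

#' Default marginal distributions for the synthetic cohort
#'
#' Internal table driving the generator. Continuous rows carry truncated
#' normal parameters (`mean`, `sd`, `low`, `high`); binary rows a Bernoulli
#' probability (`p`); categorical rows a level set and level probabilities.
#'
#' @return A data.frame, one row per feature.
#' @keywords internal
default_marginals <- function() {
  cont <- function(feature, group, mean, sd, low, high) {
    data.frame(feature = feature, class = "continuous", group = group,
               mean = mean, sd = sd, low = low, high = high,
               p = NA_real_, levels = NA_character_, probs = NA_character_,
               stringsAsFactors = FALSE)
  }
  bin <- function(feature, group, p) {
    data.frame(feature = feature, class = "binary", group = group,
               mean = NA_real_, sd = NA_real_, low = NA_real_, high = NA_real_,
               p = p, levels = NA_character_, probs = NA_character_,
               stringsAsFactors = FALSE)
  }
  cat_ <- function(feature, group, levels, probs) {
    data.frame(feature = feature, class = "categorical", group = group,
               mean = NA_real_, sd = NA_real_, low = NA_real_, high = NA_real_,
               p = NA_real_, levels = paste(levels, collapse = ","),
               probs = paste(probs, collapse = ","),
               stringsAsFactors = FALSE)
  }

  clinical <- rbind(
    cont("age", "clinical", 70, 13, 45, 89),
    cont("bmi", "clinical", 26.5, 5, 14, 39),
    cont("asa_physical_status", "clinical", 2.3, 0.7, 0, 4),
    cont("dasi", "clinical", 45, 12, 31.4, 58.2),
    cat_("sex", "clinical", c("male", "female"), c(0.69, 0.31)),
    cat_("ethnicity", "clinical",
         c("asian", "arabic", "black", "mixed_other", "white"),
         c(0.05, 0.03, 0.07, 0.05, 0.80)),
    cat_("surgical_specialty", "clinical",
         c("colorectal", "upper_gastrointestinal", "genito_urinary",
           "head_and_neck", "thoracic", "others"),
         c(0.205, 0.165, 0.34, 0.21, 0.04, 0.04)),
    bin("hypertension", "clinical", 0.35),
    bin("diabetes", "clinical", 0.11),
    bin("angina", "clinical", 0.04),
    bin("coronary_stent", "clinical", 0.05),
    bin("cabg", "clinical", 0.03),
    bin("chronic_cardiac_failure", "clinical", 0.10),
    bin("peripheral_vascular_disease", "clinical", 0.02),
    bin("cva_tia", "clinical", 0.04),
    bin("copd", "clinical", 0.06),
    bin("asthma", "clinical", 0.08),
    bin("pulmonary_embolism", "clinical", 0.015),
    bin("pulmonary_fibrosis", "clinical", 0.01),
    bin("smoking_ex_current", "clinical", 0.36),
    bin("myocardial_ischaemia", "clinical", 0.10),
    bin("beta_blocker", "clinical", 0.20),
    bin("nitrates", "clinical", 0.03),
    bin("ace_inhibitor", "clinical", 0.18),
    bin("statin", "clinical", 0.30),
    cont("haemoglobin", "clinical", 132, 17, 70, 180),
    cont("creatinine", "clinical", 85, 25, 40, 300),
    cont("urea", "clinical", 6, 2, 1.5, 25),
    cont("sodium", "clinical", 139, 3, 125, 150),
    cont("potassium", "clinical", 4.3, 0.4, 3, 6),
    cont("albumin", "clinical", 41, 4, 20, 52),
    cont("white_cell_count", "clinical", 7.5, 2.2, 2, 20),
    cont("platelets", "clinical", 265, 75, 50, 600),
    cont("egfr", "clinical", 78, 17, 15, 120),
    cont("crp", "clinical", 8, 10, 0, 150),
    cont("hba1c", "clinical", 40, 8, 25, 110),
    cont("bilirubin", "clinical", 10, 5, 2, 60),
    cont("alt", "clinical", 24, 12, 5, 150),
    cont("alkaline_phosphatase", "clinical", 85, 30, 30, 400)
  )

  fitness <- rbind(
    cont("mets", "fitness", 4.6, 1.4, 1.47, 10.7),
    cont("at_vo2", "fitness", 10.7, 2.6, 2.9, 25),
    cont("peak_vo2", "fitness", 17.3, 5, 8.2, 46),
    cont("peak_ve_vco2", "fitness", 35, 5.5, 17.5, 56),
    cont("at_ve_vco2", "fitness", 33, 5, 18, 60),
    cont("rest_ve_vco2", "fitness", 40, 7, 20, 70),
    cont("peak_ve_vo2", "fitness", 37, 6.5, 18, 65),
    cont("at_ve_vo2", "fitness", 29, 5, 15, 55),
    cont("rest_ve_vo2", "fitness", 42, 8, 20, 75),
    cont("peak_o2_pulse", "fitness", 10.5, 3, 3, 25),
    cont("at_o2_pulse", "fitness", 8.5, 2.5, 2.5, 20),
    cont("rest_o2_pulse", "fitness", 4, 1.2, 1, 10),
    cont("peak_hr", "fitness", 135, 20, 80, 190),
    cont("at_hr", "fitness", 105, 15, 60, 160),
    cont("rest_hr", "fitness", 75, 12, 40, 120),
    cont("hr_reserve", "fitness", 60, 18, 5, 120),
    cont("hrr_1min", "fitness", 15, 8, 0, 50),
    cont("peak_work_rate", "fitness", 110, 35, 20, 250),
    cont("at_work_rate", "fitness", 60, 22, 10, 160),
    cont("peak_ve", "fitness", 65, 18, 20, 140),
    cont("at_ve", "fitness", 35, 10, 12, 90),
    cont("rest_ve", "fitness", 11, 3, 5, 25),
    cont("peak_vt", "fitness", 1.9, 0.5, 0.6, 3.8),
    cont("at_vt", "fitness", 1.5, 0.4, 0.5, 3.2),
    cont("rest_vt", "fitness", 0.7, 0.2, 0.3, 1.6),
    cont("peak_bf", "fitness", 34, 7, 15, 60),
    cont("at_bf", "fitness", 24, 5, 10, 45),
    cont("rest_bf", "fitness", 16, 4, 8, 30),
    cont("peak_rer", "fitness", 1.12, 0.1, 0.8, 1.5),
    cont("at_rer", "fitness", 0.95, 0.07, 0.7, 1.2),
    cont("rest_rer", "fitness", 0.85, 0.07, 0.6, 1.1),
    cont("peak_petco2", "fitness", 4.6, 0.7, 2.5, 7),
    cont("at_petco2", "fitness", 5.0, 0.6, 3, 7.5),
    cont("rest_petco2", "fitness", 4.7, 0.5, 3, 6.5),
    cont("peak_peto2", "fitness", 15.5, 1, 12, 19),
    cont("at_peto2", "fitness", 14.3, 1, 11, 18),
    cont("rest_peto2", "fitness", 14.8, 1, 11.5, 18.5),
    cont("peak_vco2", "fitness", 1.8, 0.6, 0.5, 4.5),
    cont("at_vco2", "fitness", 1.0, 0.35, 0.3, 3),
    cont("rest_vco2", "fitness", 0.25, 0.07, 0.1, 0.6),
    cont("peak_spo2", "fitness", 96, 2.5, 80, 100),
    cont("rest_spo2", "fitness", 97, 1.5, 85, 100),
    cont("vo2_wr_slope", "fitness", 9.8, 1.5, 4, 16),
    cont("oues", "fitness", 1.9, 0.6, 0.5, 4),
    cont("fev1", "fitness", 2.4, 0.7, 0.7, 5),
    cont("fvc", "fitness", 3.4, 0.9, 1, 6.5)
  )

  rbind(clinical, fitness)
}

#' Default planted outcome effects
#'
#' The outcome mechanism plants the effect directions reported for this
#' risk model: poorer ventilatory efficiency (higher peak VE/VCO2) raises
#' risk; BMI above 28 kg/m^2 is protective (obesity paradox); ventilatory
#' equivalent for oxygen above 38 is protective; prior myocardial ischaemia
#' raises risk.
#'
#' @return A data.frame with columns `feature`, `transform`
#'   (`linear`, `threshold_above`, `threshold_below`), `threshold`
#'   (centre for `linear`, cut-point otherwise, in feature units) and
#'   `coef` (log-odds scale).
#' @export
default_effects <- function() {
  data.frame(
    feature = c("peak_ve_vco2", "bmi", "peak_ve_vo2", "myocardial_ischaemia"),
    transform = c("linear", "threshold_above", "threshold_above", "linear"),
    threshold = c(34.5, 28, 38, 0),
    coef = c(0.15, -0.8, -0.6, 0.7),
    stringsAsFactors = FALSE
  )
}
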