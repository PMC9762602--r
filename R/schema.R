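#' Default questionnaire feature schema
#'
#' Builds the feature metadata table the cohort generator and downstream
#' modules assume: 122 features in four questionnaire blocks -- BLINE
#' (baseline, 2 features), HLQ (health and lifestyle, 56), CDHQ1 (diet
#' history, 52) and PYTPAQ (past-year physical activity, 12) -- of which 98
#' are actionable lifestyle features and 24 intrinsic (age, reproductive
#' history, medical history and the like).
#'
#' Each row describes one feature: its name, block, type (numeric or
#' categorical), whether it is actionable, and its admissible range (numeric
#' min/max, or the category set encoded as a comma-separated string).
#'
#' @return A data.frame with columns \code{name}, \code{block}, \code{dtype},
#'   \code{actionable}, \code{min}, \code{max}, \code{levels} (NA for
#'   numeric features) and one row per feature.
#' @export
default_feature_schema <- function() {
  rows <- list()
  num <- function(name, block, actionable, min = 0, max = 10) {
    data.frame(name = name, block = block, dtype = "numeric",
               actionable = actionable, min = min, max = max,
               levels = NA_character_, stringsAsFactors = FALSE)
  }
  cat_ <- function(name, block, actionable, levels) {
    data.frame(name = name, block = block, dtype = "categorical",
               actionable = actionable, min = NA_real_, max = NA_real_,
               levels = paste(levels, collapse = ","),
               stringsAsFactors = FALSE)
  }

  ## BLINE: age (intrinsic), urban/rural residence (actionable)
  rows <- c(rows, list(
    num("BLINE_AGE_AT_BASELINE", "BLINE", FALSE, 35, 70),
    cat_("BLINE_GEO_AREA", "BLINE", TRUE, c("urban", "rural"))
  ))

  ## HLQ: 56 features. 23 intrinsic (medical/reproductive/demographic
  ## history) + 33 actionable (smoking, social support, anthropometrics).
  hlq <- list(
    num("HLQ_FRH_1", "HLQ", FALSE, 9, 17),           # age at menarche
    num("HLQ_FRH_25", "HLQ", FALSE, 0, 1),           # hormone repl. hist. 0/1
    num("HLQ_FRH_3", "HLQ", FALSE, 0, 8),            # parity
    num("HLQ_FRH_8", "HLQ", FALSE, 15, 45)           # age at first birth
  )
  for (i in seq_len(11)) {
    hlq <- c(hlq, list(cat_(sprintf("HLQ_MED_%d", i), "HLQ", FALSE,
                            c("no", "yes"))))          # medical history items
  }
  for (i in seq_len(5)) {
    hlq <- c(hlq, list(cat_(sprintf("HLQ_FAM_%d", i), "HLQ", FALSE,
                            c("no", "yes"))))          # family cancer history
  }
  for (i in seq_len(3)) {
    hlq <- c(hlq, list(num(sprintf("HLQ_SCR_%d", i), "HLQ", FALSE, 0, 20)))
  }                                                    # screening counts
  # 4 + 11 + 5 + 3 = 23 intrinsic; now 33 actionable
  hlq <- c(hlq, list(
    num("HLQ_SPT_11", "HLQ", TRUE, 0, 30),             # connection index
    num("HLQ_SPT_16", "HLQ", TRUE, 0, 30),             # share index
    cat_("HLQ_SMK_1", "HLQ", TRUE, c("never", "former", "current")),
    num("HLQ_SMK_2", "HLQ", TRUE, 0, 40),              # pack-years
    num("HLQ_ANT_1", "HLQ", TRUE, 15, 45),             # BMI
    num("HLQ_ANT_2", "HLQ", TRUE, 55, 130)             # waist circumference
  ))
  for (i in seq_len(18)) {
    hlq <- c(hlq, list(num(sprintf("HLQ_SPT_%d", 16 + i), "HLQ", TRUE, 0, 30)))
  }                                                    # other support items
  for (i in seq_len(9)) {
    hlq <- c(hlq, list(num(sprintf("HLQ_LIF_%d", i), "HLQ", TRUE, 0, 10)))
  }                                                    # lifestyle scales
  stopifnot(length(hlq) == 56)
  rows <- c(rows, hlq)

  ## CDHQ1: 52 diet/supplement features, all actionable.
  cdhq <- list(
    num("CDHQ1_SELENIUM_SPL", "CDHQ1", TRUE, 0, 47),
    num("CDHQ1_VITAMIN_E_SPL", "CDHQ1", TRUE, 0, 1000),
    num("CDHQ1_ORANGE_VEG_MYP", "CDHQ1", TRUE, 0, 2.31),
    num("CDHQ1_FISH_HI_MYP", "CDHQ1", TRUE, 0, 3),
    num("CDHQ1_WHOLE_GRAIN_MYP", "CDHQ1", TRUE, 0, 8),
    num("CDHQ1_ALCOHOL_MYP", "CDHQ1", TRUE, 0, 10),
    cat_("CDHQ1_DIET_TYPE", "CDHQ1", TRUE,
         c("omnivore", "vegetarian", "pescatarian"))
  )
  for (i in seq_len(45)) {
    cdhq <- c(cdhq, list(num(sprintf("CDHQ1_NUTR_%d", i), "CDHQ1", TRUE,
                             0, 100)))
  }
  stopifnot(length(cdhq) == 52)
  rows <- c(rows, cdhq)

  ## PYTPAQ: 12 physical-activity features, all actionable.
  pyt <- list(cat_("PYTPAQ_ACTIVE_JOB", "PYTPAQ", TRUE, c("no", "yes")))
  for (i in seq_len(11)) {
    pyt <- c(pyt, list(num(sprintf("PYTPAQ_ACT_%d", i), "PYTPAQ", TRUE,
                           0, 60)))
  }
  rows <- c(rows, pyt)

  schema <- do.call(rbind, rows)
  rownames(schema) <- NULL
  stopifnot(nrow(schema) == 122L,
            sum(schema$actionable) == 98L,
            identical(as.integer(table(factor(schema$block,
              levels = c("BLINE", "HLQ", "CDHQ1", "PYTPAQ")))),
              c(2L, 56L, 52L, 12L)))
  schema
}

#' Risk-model features and their true coefficients
#'
#' The generator's sparse linear risk structure uses ten features (the ones
#' an elastic-net Cox fit retains on real data of this kind), with signs:
#' positive for age at recruitment, connection and share indices, hormone
#' replacement history, whole-grain consumption and vitamin E intake;
#' negative for selenium intake, orange-vegetable and high-omega-3 fish
#' consumption, and age at menarche. Magnitudes are on the standardized
#' feature scale (log-hazard per SD), 0.15-0.30, i.e. hazard ratios of
#' roughly 1.16-1.35 per SD.
#'
#' @return Named numeric vector of true log-hazard coefficients.
#' @export
default_beta <- function() {
  c(BLINE_AGE_AT_BASELINE = 0.30,
    CDHQ1_SELENIUM_SPL = -0.25,
    HLQ_SPT_11 = 0.20,
    CDHQ1_ORANGE_VEG_MYP = -0.20,
    CDHQ1_FISH_HI_MYP = -0.20,
    HLQ_FRH_1 = -0.20,
    HLQ_SPT_16 = 0.15,
    HLQ_FRH_25 = 0.15,
    CDHQ1_WHOLE_GRAIN_MYP = 0.15,
    CDHQ1_VITAMIN_E_SPL = 0.15)
}

schema_levels <- function(schema, name) {
  lv <- schema$levels[schema$name == name]
  strsplit(lv, ",", fixed = TRUE)[[1]]
}
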