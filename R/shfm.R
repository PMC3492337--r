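#' Seattle Heart Failure Model coefficient table (synthetic transcription)
#'
#' The SHFM is a published multivariable proportional-hazards risk score
#' for heart failure survival whose linear predictor combines transformed
#' covariates: male sex, age/10, NYHA class, 100/LVEF, systolic blood
#' pressure/10, (138 - serum sodium), 100/total cholesterol,
#' |16 - hemoglobin|, percent lymphocytes, uric acid, diuretic dose
#' (mg/kg), etiology and medication/device flags.  One unit of score
#' corresponds to a hazard ratio of roughly e.
#'
#' The exact published coefficient values are not redistributable here, so
#' this table is a clearly versioned SYNTHETIC stand-in: signs and rough
#' magnitudes follow the published model, and the intercept/baseline
#' survival are calibrated so a typical NYHA III HFREF patient scores near
#' 0 with ~10% predicted one-year mortality.  Every analysis in this
#' package depends only on the structure of the score (linearity, the
#' beta-blocker toggle, the lymphocyte imputation rule), never on these
#' numeric values, and the table can be overridden with
#' [read_shfm_coefficients()].
#'
#' @return named list of class `shfm_coefficients`
#' @export
shfm_default_coefficients <- function() {
  structure(list(
    version = "synthetic-1.0",
    intercept = -3.30,
    age_per_decade = 0.30,
    male = 0.20,
    nyha_per_class = 0.40,
    lvef_inv = 0.33,        # per unit of 100/LVEF
    sbp_per_10 = -0.15,     # per 10 mm Hg
    sodium_deficit = 0.05,  # per mEq/L below 138
    cholesterol_inv = 0.40, # per unit of 100/cholesterol
    hgb_deviation = 0.08,   # per g/dL of |16 - hemoglobin|
    lymphocyte_pct = -0.025,
    uric_acid = 0.07,
    diuretic_mg_kg = 0.30,
    ischemic = 0.25,
    acei = -0.25,
    beta_blocker = -0.35,
    arb = -0.20,
    statin = -0.40,
    allopurinol = 0.30,
    aldosterone_blocker = -0.15,
    baseline_survival_1y = 0.90
  ), class = "shfm_coefficients")
}

#' Read / write an SHFM coefficient table (JSON config)
#'
#' @param path file path
#' @export
read_shfm_coefficients <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- shfm_default_coefficients()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown))
    stopf("unknown SHFM coefficient field(s): %s",
          paste(unknown, collapse = ", "))
  defaults[names(raw)] <- raw
  structure(defaults, class = "shfm_coefficients")
}

#' @rdname read_shfm_coefficients
#' @param coefs an `shfm_coefficients` list
#' @export
write_shfm_coefficients <- function(coefs, path) {
  jsonlite::write_json(unclass(coefs), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

shfm_required <- c("age_years", "male", "lvef_pct", "sbp_mmhg",
                   "sodium_meq_l", "total_cholesterol_mg_dl",
                   "hemoglobin_g_dl")

#' Compute the SHFM score and predicted one-year survival
#'
#' The score is the linear combination of transformed covariates under the
#' coefficient table.  Percent lymphocytes defaults to 25 when absent (the
#' value imputed when scoring trial populations lacking the measurement).
#' Predicted one-year survival uses the proportional-hazards transform
#' `S0^exp(score)`; one-year mortality is its complement.  Excluding the
#' beta-blocker coefficient makes the score invariant to the beta-blocker
#' flag; including it shifts the score by exactly that coefficient when the
#' flag is set.
#'
#' @param input named list / one-row data.frame of covariates:
#'   `age_years`, `male` (0/1), `nyha_class` (defaults 3), `lvef_pct`,
#'   `sbp_mmhg`, `sodium_meq_l`, `total_cholesterol_mg_dl`,
#'   `hemoglobin_g_dl`, `lymphocyte_pct` (defaults 25), `uric_acid_mg_dl`
#'   (defaults 7), `diuretic_mg_kg` (defaults 1), `ischemic` and
#'   medication flags (`acei`, `beta_blocker`, `arb`, `statin`,
#'   `allopurinol`, `aldosterone_blocker`; default 0)
#' @param include_beta_blocker include the beta-blocker coefficient?
#' @param coefs coefficient table ([shfm_default_coefficients()])
#' @return list of class `shfm_score`: `score`, `one_year_survival`,
#'   `one_year_mortality`, `beta_blocker_included`
#' @export
shfm_score <- function(input, include_beta_blocker = TRUE,
                       coefs = shfm_default_coefficients()) {
  input <- as.list(input)
  miss <- shfm_required[!vapply(shfm_required, function(f)
    !is.null(input[[f]]) && !all(is.na(input[[f]])), TRUE)]
  if (length(miss))
    stopf("SHFM scoring: missing required field(s): %s",
          paste(miss, collapse = ", "))
  g <- function(f, default = 0) {
    v <- input[[f]]
    if (is.null(v)) rep(default, length(input$age_years))
    else ifelse(is.na(v), default, v)
  }
  out_of_range <- c(
    if (any(input$lvef_pct <= 0 | input$lvef_pct > 100)) "lvef_pct",
    if (any(input$sbp_mmhg < 50 | input$sbp_mmhg > 260)) "sbp_mmhg",
    if (any(input$sodium_meq_l < 110 | input$sodium_meq_l > 160)) "sodium_meq_l")
  if (length(out_of_range))
    warning(sprintf("SHFM input outside physiologic range: %s",
                    paste(out_of_range, collapse = ", ")), call. = FALSE)
  score <- coefs$intercept +
    coefs$age_per_decade * input$age_years / 10 +
    coefs$male * input$male +
    coefs$nyha_per_class * g("nyha_class", 3) +
    coefs$lvef_inv * 100 / input$lvef_pct +
    coefs$sbp_per_10 * input$sbp_mmhg / 10 +
    coefs$sodium_deficit * (138 - input$sodium_meq_l) +
    coefs$cholesterol_inv * 100 / input$total_cholesterol_mg_dl +
    coefs$hgb_deviation * abs(16 - input$hemoglobin_g_dl) +
    coefs$lymphocyte_pct * g("lymphocyte_pct", 25) +
    coefs$uric_acid * g("uric_acid_mg_dl", 7) +
    coefs$diuretic_mg_kg * g("diuretic_mg_kg", 1) +
    coefs$ischemic * g("ischemic") +
    coefs$acei * g("acei") +
    coefs$arb * g("arb") +
    coefs$statin * g("statin") +
    coefs$allopurinol * g("allopurinol") +
    coefs$aldosterone_blocker * g("aldosterone_blocker") +
    if (include_beta_blocker) coefs$beta_blocker * g("beta_blocker") else 0
  surv <- coefs$baseline_survival_1y ^ exp(score)
  structure(list(score = score,
                 one_year_survival = surv,
                 one_year_mortality = 1 - surv,
                 beta_blocker_included = include_beta_blocker),
            class = "shfm_score")
}

#' Score a whole cohort with the SHFM
#'
#' Vectorised [shfm_score()] over a cohort data.frame.  Hemoglobin is
#' derived from hematocrit (`hematocrit_pct / 3`) when no
#' `hemoglobin_g_dl` column is present, sex is mapped from the `sex`
#' column, and the beta-blocker flag is taken from the randomised arm
#' (active arm = on beta-blocker) unless a `beta_blocker` column exists.
#'
#' @param cohort data.frame with the cohort schema
#' @inheritParams shfm_score
#' @return data.frame with `shfm_score` and `shfm_mort1y` columns
#' @export
score_cohort <- function(cohort, include_beta_blocker = TRUE,
                         coefs = shfm_default_coefficients()) {
  input <- list(
    age_years = cohort$age_years,
    male = if (!is.null(cohort$male)) cohort$male
           else as.integer(cohort$sex == "male"),
    nyha_class = cohort$nyha_class,
    lvef_pct = cohort$lvef_pct %||% cohort$lvef_baseline_pct,
    sbp_mmhg = cohort$sbp_mmhg,
    sodium_meq_l = cohort$sodium_meq_l,
    total_cholesterol_mg_dl = cohort$total_cholesterol_mg_dl,
    hemoglobin_g_dl = cohort$hemoglobin_g_dl %||%
      (cohort$hematocrit_pct / 3),
    lymphocyte_pct = cohort$lymphocyte_pct,
    uric_acid_mg_dl = cohort$uric_acid_mg_dl,
    diuretic_mg_kg = cohort$diuretic_mg_kg,
    ischemic = cohort$ischemic,
    acei = cohort$acei,
    beta_blocker = cohort$beta_blocker %||%
      as.integer(cohort$treatment != "placebo"),
    arb = cohort$arb, statin = cohort$statin,
    allopurinol = cohort$allopurinol,
    aldosterone_blocker = cohort$aldosterone_blocker)
  sc <- shfm_score(input, include_beta_blocker, coefs)
  data.frame(shfm_score = sc$score, shfm_mort1y = sc$one_year_mortality)
}
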