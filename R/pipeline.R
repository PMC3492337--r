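#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()].  A seed is mandatory:
#' every stochastic stage derives its RNG stream from it, making the whole
#' pipeline a pure function of (input data, config).
#'
#' @param seed integer seed (required)
#' @param cohort patient-level data.frame; `NULL` to generate a synthetic
#'   cohort from `generator`
#' @param generator a [default_params()] object used when `cohort` is NULL
#' @param n synthetic cohort size (defaults to `generator$n`)
#' @param k_a,k_b fixed class counts; `NULL` runs model-order selection
#' @param k_range candidate class counts for selection
#' @param n_starts EM restarts per fit
#' @param tol,max_iter EM convergence settings
#' @param shfm_coefs SHFM coefficient table
#' @param nri_thresholds list with elements `mort1y` and `resp`: risk
#'   category cut points for the categorical NRI
#' @param loocv run leave-one-out cross-validation for every model
#'   combination (slow)?
#' @param out_dir output directory; `NULL` for no file output
#' @return list of class `pipeline_config`
#' @export
pipeline_config <- function(seed, cohort = NULL,
                            generator = default_params(), n = NULL,
                            k_a = NULL, k_b = NULL, k_range = 2:10,
                            n_starts = 10L, tol = 1e-8, max_iter = 5000L,
                            shfm_coefs = shfm_default_coefficients(),
                            nri_thresholds = list(mort1y = c(0.05, 0.15),
                                                  resp = c(0.20, 0.40)),
                            loocv = FALSE, out_dir = NULL) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(as.integer(seed))))
    stopf("pipeline_config: an integer seed is required")
  structure(list(seed = as.integer(seed), cohort = cohort,
                 generator = generator, n = n %||% generator$n,
                 k_a = k_a, k_b = k_b, k_range = k_range,
                 n_starts = as.integer(n_starts), tol = tol,
                 max_iter = as.integer(max_iter), shfm_coefs = shfm_coefs,
                 nri_thresholds = nri_thresholds, loocv = loocv,
                 out_dir = out_dir), class = "pipeline_config")
}

## the seven model combinations evaluated for every outcome
model_combinations <- function() {
  list(SHFM = "shfm_score",
       `LCM A` = "subtype_a",
       `LCM B` = "subtype_b",
       `A+B` = c("subtype_a", "subtype_b"),
       `SHFM+A` = c("shfm_score", "subtype_a"),
       `SHFM+B` = c("shfm_score", "subtype_b"),
       All = c("shfm_score", "subtype_a", "subtype_b"))
}

combo_formula <- function(lhs, covariates) {
  stats::as.formula(paste(lhs, "~ treatment +",
                          paste(covariates, collapse = " + ")))
}

#' Evaluate the model-combination grid
#'
#' Fits, for each of the seven predictor combinations (SHFM, LCM A, LCM B,
#' A+B, SHFM+A, SHFM+B, All; treatment always included), the Cox model for
#' cumulative mortality and logistic models for one-year mortality and
#' LVEF response, and returns apparent (and optionally LOOCV) c-indices.
#'
#' @param df analysis data.frame with columns `treatment` (0/1),
#'   `subtype_a`, `subtype_b` (factors), `shfm_score`, `followup_days`,
#'   `death`, `death_1y`, `lvef_response`
#' @param loocv also compute LOOCV c-indices?
#' @return list: `table` (one row per combination), `fits` (per combo per
#'   outcome), `predictions` (per combo per outcome)
#' @export
evaluate_combinations <- function(df, loocv = FALSE) {
  combos <- model_combinations()
  fits <- list(); preds <- list()
  rows <- lapply(names(combos), function(nm) {
    cov <- combos[[nm]]
    f_cox <- combo_formula("survival::Surv(followup_days, death)", cov)
    f_m1 <- combo_formula("death_1y", cov)
    f_rs <- combo_formula("lvef_response", cov)
    cox <- survival::coxph(f_cox, data = df, ties = "efron")
    g1 <- stats::glm(f_m1, stats::binomial(), data = df)
    g2 <- stats::glm(f_rs, stats::binomial(), data = df)
    lp <- unname(stats::predict(cox, type = "lp"))
    p1 <- unname(stats::fitted(g1))
    p2 <- unname(stats::fitted(g2))
    fits[[nm]] <<- list(cum_mort = cox, mort1y = g1, resp = g2)
    preds[[nm]] <<- list(cum_mort = lp, mort1y = p1, resp = p2)
    row <- data.frame(
      model = nm,
      c_cum_mort = harrell_c(df$followup_days, df$death, lp),
      c_mort1y = binary_c(df$death_1y, p1),
      c_resp = binary_c(df$lvef_response, p2))
    if (loocv) {
      row$c_cum_mort_loocv <- loocv_c(f_cox, df, "cox")$c
      row$c_mort1y_loocv <- loocv_c(f_m1, df, "binomial")$c
      row$c_resp_loocv <- loocv_c(f_rs, df, "binomial")$c
    }
    row
  })
  list(table = do.call(rbind, rows), fits = fits, predictions = preds)
}

pipeline_log <- function(lines, stage, msg) {
  c(lines, sprintf("[%s] %s: %s",
                   format(Sys.time(), "%Y-%m-%d %H:%M:%S"), stage, msg))
}

#' Run the full subtype-discovery pipeline
#'
#' Stages: obtain cohort (supplied or synthetic) -> encode both variable
#' sets -> select or fix the class counts -> fit both latent class models
#' -> Bayesian subtype assignment -> SHFM scoring (without the
#' beta-blocker coefficient for treatment-effect analyses) ->
#' subtype-by-arm outcome tables -> seven-model-combination evaluation for
#' the three outcomes -> NRI of adding the latent class models to SHFM.
#' When `config$out_dir` is set, every table is written as CSV, models as
#' JSON, plus the config snapshot and a timestamped log.
#'
#' @param config a [pipeline_config()]
#' @return list of class `run_report`
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stopf("run_pipeline expects a pipeline_config")
  log <- character()
  stage <- function(nm, expr) {
    log <<- pipeline_log(log, nm, "start")
    tryCatch(expr,
             error = function(e) stopf("pipeline stage '%s' failed: %s",
                                       nm, conditionMessage(e)))
  }
  cohort <- stage("cohort", {
    if (!is.null(config$cohort)) config$cohort
    else generate_cohort(config$generator, n = config$n, seed = config$seed)
  })
  cb <- default_codebook()
  resp_a <- stage("encode", encode_cohort(cohort, cb, "A"))
  resp_b <- encode_cohort(cohort, cb, "B")
  log <- pipeline_log(log, "encode",
                      sprintf("complete cases: LCM A %d/%d, LCM B %d/%d",
                              sum(rowSums(resp_a$missing) == 0),
                              nrow(resp_a$values),
                              sum(rowSums(resp_b$missing) == 0),
                              nrow(resp_b$values)))
  fit_side <- function(resp, k_fixed, seed_off) {
    if (!is.null(k_fixed)) {
      list(fit = fit_lca(resp, k_fixed, n_starts = config$n_starts,
                         seed = config$seed + seed_off, tol = config$tol,
                         max_iter = config$max_iter),
           selection = NULL)
    } else {
      sel <- select_num_classes(resp, config$k_range,
                                n_starts = config$n_starts,
                                seed = config$seed + seed_off,
                                tol = config$tol,
                                max_iter = config$max_iter)
      list(fit = sel$fit, selection = sel)
    }
  }
  side_a <- stage("lcm_a", fit_side(resp_a, config$k_a, 100L))
  side_b <- stage("lcm_b", fit_side(resp_b, config$k_b, 200L))
  log <- pipeline_log(log, "lcm",
                      sprintf("K_A = %d, K_B = %d", side_a$fit$model$K,
                              side_b$fit$model$K))
  asg_a <- stage("assign", assign_subtype(side_a$fit, resp_a))
  asg_b <- assign_subtype(side_b$fit, resp_b)
  shfm <- stage("shfm", score_cohort(cohort, include_beta_blocker = FALSE,
                                     coefs = config$shfm_coefs))
  outcomes <- cohort[c("treatment", "followup_days", "death", "death_1y",
                       "lvef_response")]
  tab_a <- stage("outcome_tables",
                 subtype_outcome_table(asg_a$label, outcomes, prefix = "A"))
  tab_b <- subtype_outcome_table(asg_b$label, outcomes, prefix = "B")
  df <- data.frame(treatment = as.integer(cohort$treatment != "placebo"),
                   subtype_a = factor(asg_a$label),
                   subtype_b = factor(asg_b$label),
                   shfm_score = shfm$shfm_score,
                   followup_days = cohort$followup_days,
                   death = cohort$death, death_1y = cohort$death_1y,
                   lvef_response = cohort$lvef_response)
  comps <- stage("model_comparison", evaluate_combinations(df, config$loocv))
  nri_pairs <- list(c("SHFM", "SHFM+A"), c("SHFM", "SHFM+B"),
                    c("SHFM", "All"))
  nris <- stage("nri", lapply(nri_pairs, function(pr) {
    list(pair = pr,
         mort1y = nri(comps$predictions[[pr[1]]]$mort1y,
                      comps$predictions[[pr[2]]]$mort1y, df$death_1y,
                      config$nri_thresholds$mort1y),
         resp = nri(comps$predictions[[pr[1]]]$resp,
                    comps$predictions[[pr[2]]]$resp, df$lvef_response,
                    config$nri_thresholds$resp))
  }))
  log <- pipeline_log(log, "done", "pipeline complete")
  report <- structure(list(
    config = config, cohort = cohort,
    selection_a = side_a$selection, selection_b = side_b$selection,
    fit_a = side_a$fit, fit_b = side_b$fit,
    assignment_a = asg_a, assignment_b = asg_b,
    shfm = shfm, outcome_table_a = tab_a, outcome_table_b = tab_b,
    comparison = comps$table, fits = comps$fits,
    predictions = comps$predictions, nri = nris, log = log),
    class = "run_report")
  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> n = %d, K_A = %d, K_B = %d\n",
              nrow(x$cohort), x$fit_a$model$K, x$fit_b$model$K))
  print(x$comparison, row.names = FALSE)
  invisible(x)
}

write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  cfg <- report$config
  cfg$cohort <- NULL; cfg$shfm_coefs <- unclass(cfg$shfm_coefs)
  cfg$generator <- NULL   # large; the seed and n reproduce it
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  write_cohort(report$cohort, p("cohort.csv"))
  for (s in c("a", "b")) {
    sel <- report[[paste0("selection_", s)]]
    if (!is.null(sel))
      utils::write.csv(sel$diagnostics, p(sprintf("selection_%s.csv", s)),
                       row.names = FALSE)
    write_lca_model(report[[paste0("fit_", s)]], p(sprintf("lcm_%s.json", s)))
    utils::write.csv(report[[paste0("outcome_table_", s)]],
                     p(sprintf("outcomes_%s.csv", s)), row.names = FALSE)
  }
  assign_df <- data.frame(subtype_a = report$assignment_a$label,
                          subtype_b = report$assignment_b$label,
                          report$shfm)
  utils::write.csv(assign_df, p("assignments.csv"), row.names = FALSE)
  utils::write.csv(report$comparison, p("model_comparison.csv"),
                   row.names = FALSE)
  nri_rows <- do.call(rbind, lapply(report$nri, function(x)
    do.call(rbind, lapply(c("mort1y", "resp"), function(oc) {
      r <- x[[oc]]$categorical
      data.frame(baseline = x$pair[1], updated = x$pair[2], outcome = oc,
                 nri_event = r$event, nri_nonevent = r$nonevent,
                 nri_overall = r$overall,
                 nri_continuous = x[[oc]]$continuous$overall)
    }))))
  utils::write.csv(nri_rows, p("nri.csv"), row.names = FALSE)
  writeLines(report$log, p("run.log"))
  invisible(out_dir)
}

#' Apply frozen models to an external cohort
#'
#' No refitting: the external cohort is encoded with the codebook, each
#' subject is assigned to the frozen latent class models' subtypes by
#' Bayes' rule, SHFM scores are computed, and the stored outcome
#' regressions predict each subject's risks.  Evaluation metrics are
#' computed on the external cohort when it carries outcome columns.  This
#' is the external-validation path (derive on one trial, test on another).
#'
#' @param report a `run_report` from [run_pipeline()]
#' @param cohort external patient-level data.frame satisfying the same
#'   schema
#' @return list: `assignment_a`, `assignment_b`, `shfm`, `predictions`
#'   (per combination per outcome), `comparison` (c-index table, when
#'   outcomes are present)
#' @export
apply_frozen_models <- function(report, cohort) {
  cb <- default_codebook()
  resp_a <- encode_cohort(cohort, cb, "A")
  resp_b <- encode_cohort(cohort, cb, "B")
  asg_a <- assign_subtype(report$fit_a, resp_a)
  asg_b <- assign_subtype(report$fit_b, resp_b)
  shfm <- score_cohort(cohort, include_beta_blocker = FALSE,
                       coefs = report$config$shfm_coefs)
  df <- data.frame(treatment = as.integer(cohort$treatment != "placebo"),
                   subtype_a = factor(asg_a$label,
                                      levels = seq_len(report$fit_a$model$K)),
                   subtype_b = factor(asg_b$label,
                                      levels = seq_len(report$fit_b$model$K)),
                   shfm_score = shfm$shfm_score)
  preds <- lapply(report$fits, function(f3)
    list(cum_mort = unname(cox_lp(f3$cum_mort, df)),
         mort1y = unname(stats::predict(f3$mort1y, newdata = df,
                                        type = "response")),
         resp = unname(stats::predict(f3$resp, newdata = df,
                                      type = "response"))))
  comparison <- NULL
  if (all(c("followup_days", "death", "death_1y", "lvef_response") %in%
          names(cohort))) {
    comparison <- do.call(rbind, lapply(names(preds), function(nm)
      data.frame(model = nm,
                 c_cum_mort = harrell_c(cohort$followup_days, cohort$death,
                                        preds[[nm]]$cum_mort),
                 c_mort1y = binary_c(cohort$death_1y, preds[[nm]]$mort1y),
                 c_resp = binary_c(cohort$lvef_response, preds[[nm]]$resp))))
  }
  list(assignment_a = asg_a, assignment_b = asg_b, shfm = shfm,
       predictions = preds, comparison = comparison)
}
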