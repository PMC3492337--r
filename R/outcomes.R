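#' LVEF response indicator
#'
#' Response is an improvement in LVEF of at least 5 percentage points with
#' a month-12 LVEF of at least 35%.  A missing month-12 value gives a
#' missing indicator, not a failure.
#'
#' @param baseline_lvef,month12_lvef LVEF percentages in `[0, 100]`
#' @return integer 0/1/NA vector
#' @export
lvef_response <- function(baseline_lvef, month12_lvef) {
  ok <- function(x) is.na(x) | (x >= 0 & x <= 100)
  if (!all(ok(baseline_lvef)) || !all(ok(month12_lvef)))
    stopf("LVEF values must lie in [0, 100]")
  ifelse(is.na(month12_lvef) | is.na(baseline_lvef), NA_integer_,
         as.integer(month12_lvef - baseline_lvef >= 5 & month12_lvef >= 35))
}

new_effect_estimate <- function(label, estimate, lower, upper, p,
                                measure = "OR", flags = character()) {
  structure(list(label = label, estimate = estimate, lower = lower,
                 upper = upper, p = p, measure = measure, flags = flags),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s: %s %.2f (95%% CI %.2f-%.2f), p = %.3g%s\n", x$label,
              x$measure, x$estimate, x$lower, x$upper, x$p,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","),
                                          "]") else ""))
  invisible(x)
}

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = (a d)/(b c)` where `a`/`b` are events/non-events in the exposed
#' group and `c`/`d` in the reference group.  When any cell is zero, a 0.5
#' continuity correction is added to every cell and flagged.
#'
#' @param a,b,c,d non-negative integer cell counts
#' @param conf confidence level
#' @return an `effect_estimate`
#' @export
two_by_two_odds_ratio <- function(a, b, c, d, conf = 0.95) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stopf("cell counts must be non-negative integers")
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0)
    stopf("odds ratio undefined: a margin of the 2x2 table is zero")
  flags <- character()
  if (any(cells == 0)) {
    cells <- cells + 0.5
    flags <- "continuity_corrected"
  }
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- 2 * stats::pnorm(-abs(log(or)) / se)
  new_effect_estimate("exposed vs reference", unname(or),
                      unname(exp(log(or) - z * se)),
                      unname(exp(log(or) + z * se)), unname(p),
                      "OR", flags)
}

## per-subtype treatment contrasts from a model with
## treatment * subtype interactions: effect_k = beta_treat + beta_int_k
interaction_contrasts <- function(coefs, vc, subtype_levels, trt_name,
                                  measure, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- lapply(subtype_levels, function(s) {
    v <- stats::setNames(numeric(length(coefs)), names(coefs))
    v[trt_name] <- 1
    int1 <- paste0(trt_name, ":subtype", s)
    int2 <- paste0("subtype", s, ":", trt_name)
    nm <- c(int1, int2)[c(int1, int2) %in% names(coefs)]
    if (length(nm)) v[nm[1L]] <- 1
    est <- sum(v * coefs)
    se <- sqrt(drop(t(v) %*% vc %*% v))
    new_effect_estimate(sprintf("treatment within subtype %s", s),
                        exp(est), exp(est - z * se), exp(est + z * se),
                        2 * stats::pnorm(-abs(est / se)), measure)
  })
  names(out) <- subtype_levels
  out
}

build_design <- function(data, subtype = NULL, shfm = NULL,
                         interaction = TRUE) {
  df <- data.frame(treatment = as.integer(data$treatment != "placebo"))
  rhs <- "treatment"
  if (!is.null(subtype)) {
    df$subtype <- factor(subtype)
    rhs <- paste(rhs, "+ subtype")
    if (interaction) rhs <- paste(rhs, "+ treatment:subtype")
  }
  if (!is.null(shfm)) {
    df$shfm_score <- shfm
    rhs <- paste(rhs, "+ shfm_score")
  }
  list(df = df, rhs = rhs)
}

#' Logistic outcome model with subtype x treatment interactions
#'
#' Fits `outcome ~ treatment + subtype + treatment:subtype (+ SHFM score)`
#' by maximum likelihood with Wald confidence intervals.  Per-subtype
#' treatment odds ratios are recovered from the main effect plus the
#' interaction contrast; subtype 1 is the reference.  Quasi-separation
#' (any |coefficient| above `sep_bound`) is flagged and the affected
#' intervals marked unreliable.
#'
#' @param outcome 0/1 indicator (NAs dropped)
#' @param data data.frame with a `treatment` column (`"placebo"` vs
#'   active)
#' @param subtype optional subtype labels (factor/integer)
#' @param shfm optional SHFM score covariate
#' @param interaction include treatment x subtype interactions?
#' @param sep_bound separation flag threshold on |coefficients|
#' @return list of class `outcome_fit`: `fit` (the glm), `estimates`
#'   (per-subtype treatment ORs), `fitted` (probabilities on the analysis
#'   rows), `separation` flag, `used` (row index used)
#' @export
fit_logistic <- function(outcome, data, subtype = NULL, shfm = NULL,
                         interaction = TRUE, sep_bound = 15) {
  des <- build_design(data, subtype, shfm, interaction)
  df <- cbind(y = outcome, des$df)
  used <- which(stats::complete.cases(df))
  df <- df[used, , drop = FALSE]
  fit <- stats::glm(stats::as.formula(paste("y ~", des$rhs)),
                    family = stats::binomial(), data = df)
  coefs <- stats::coef(fit)
  separation <- any(abs(coefs) > sep_bound, na.rm = TRUE)
  estimates <- NULL
  if (!is.null(subtype)) {
    lev <- levels(df$subtype)
    estimates <- interaction_contrasts(coefs, stats::vcov(fit),
                                       if (interaction) lev else lev[1L],
                                       "treatment", "OR")
    if (separation)
      estimates <- lapply(estimates, function(e) {
        e$flags <- union(e$flags, "separation"); e
      })
  }
  structure(list(fit = fit, estimates = estimates,
                 fitted = stats::fitted(fit), separation = separation,
                 used = used),
            class = "outcome_fit")
}

#' Cox proportional-hazards outcome model
#'
#' Partial-likelihood estimation (Efron ties) of
#' `Surv(time, event) ~ treatment + subtype + treatment:subtype (+ SHFM)`,
#' with per-subtype treatment hazard ratios via interaction contrasts and
#' the log-rank statistic across subtypes.
#'
#' @param times follow-up times (days)
#' @param events 0/1 death indicator
#' @inheritParams fit_logistic
#' @return list of class `ph_fit`: `fit` (coxph), `estimates`,
#'   `logrank` (chi-square and p across subtypes, when given), `lp`
#'   (linear predictor), `used`
#' @export
fit_ph_model <- function(times, events, data, subtype = NULL, shfm = NULL,
                         interaction = TRUE) {
  if (any(times <= 0, na.rm = TRUE)) stopf("times must be positive")
  des <- build_design(data, subtype, shfm, interaction)
  df <- cbind(.time = times, .event = events, des$df)
  used <- which(stats::complete.cases(df))
  df <- df[used, , drop = FALSE]
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", des$rhs)),
    data = df, ties = "efron")
  estimates <- NULL
  logrank <- NULL
  if (!is.null(subtype)) {
    lev <- levels(df$subtype)
    estimates <- interaction_contrasts(stats::coef(fit), stats::vcov(fit),
                                       if (interaction) lev else lev[1L],
                                       "treatment", "HR")
    if (nlevels(df$subtype) > 1L) {
      keep <- df$subtype %in% names(which(
        tapply(df$.event, df$subtype, sum, default = 0) > 0))
      if (!all(keep))
        warning("subtype stratum without events excluded from log-rank test",
                call. = FALSE)
      sd <- survival::survdiff(survival::Surv(.time, .event) ~ subtype,
                               data = droplevels(df[keep, , drop = FALSE]))
      logrank <- list(chisq = sd$chisq,
                      df = length(sd$n) - 1L,
                      p = stats::pchisq(sd$chisq, length(sd$n) - 1L,
                                        lower.tail = FALSE))
    }
  }
  structure(list(fit = fit, estimates = estimates, logrank = logrank,
                 lp = unname(stats::predict(fit, type = "lp")),
                 used = used),
            class = "ph_fit")
}

#' Test the proportional-hazards assumption
#'
#' Scaled Schoenfeld-residual correlation test per covariate; covariates
#' with p below `alpha` are flagged for a time interaction.
#'
#' @param fit a `ph_fit` or `coxph` object
#' @param alpha flag threshold
#' @return data.frame with `covariate`, `p`, `flagged` (empty for a model
#'   with no covariates)
#' @export
test_ph_assumption <- function(fit, alpha = 0.05) {
  cox <- if (inherits(fit, "ph_fit")) fit$fit else fit
  if (length(stats::coef(cox)) == 0L)
    return(data.frame(covariate = character(), p = numeric(),
                      flagged = logical()))
  zp <- survival::cox.zph(cox)
  tab <- zp$table
  tab <- tab[rownames(tab) != "GLOBAL", , drop = FALSE]
  data.frame(covariate = rownames(tab), p = tab[, "p"],
             flagged = tab[, "p"] < alpha, row.names = NULL)
}

#' Add covariate x log(time) interactions for PH violations
#'
#' Refits the proportional-hazards model with a time-varying effect
#' `x * log(t)` (t in years) for each flagged covariate and returns an
#' `HR(t) = exp(beta + gamma log t)` evaluator.  With time in years the
#' main-effect coefficient is the log hazard ratio at one year.
#'
#' @param times,events,data,subtype,shfm as in [fit_ph_model()]
#' @param covariates character vector of design-column names to give
#'   time-varying effects (e.g. `"subtype2"`)
#' @return list of class `tv_ph_fit`: `fit`, `hr_at` (function of
#'   covariate name and time in years), `geometric_mean_years` (of the
#'   observed event times), `hr_table` (HRs at 1, 2, 3 years and at the
#'   geometric mean)
#' @export
add_time_interaction <- function(times, events, data, covariates,
                                 subtype = NULL, shfm = NULL) {
  if (!length(covariates)) stopf("no covariates flagged for time interaction")
  des <- build_design(data, subtype, shfm, interaction = FALSE)
  mm <- stats::model.matrix(stats::as.formula(paste("~", des$rhs)), des$df)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  bad <- setdiff(covariates, colnames(mm))
  if (length(bad)) stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  df <- data.frame(.time = times / 365.25, .event = events, mm,
                   check.names = FALSE)
  used <- which(stats::complete.cases(df))
  df <- df[used, , drop = FALSE]
  main <- paste(sprintf("`%s`", colnames(mm)), collapse = " + ")
  tts <- paste(sprintf("tt(`%s`)", covariates), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~", main, "+", tts)),
    data = df, ties = "efron",
    tt = function(x, t, ...) x * log(t))
  cf <- stats::coef(fit)
  hr_at <- function(covariate, t_years) {
    b <- cf[[covariate]]
    tt_nm <- intersect(c(sprintf("tt(`%s`)", covariate),
                         sprintf("tt(%s)", covariate)), names(cf))
    g <- if (length(tt_nm)) cf[[tt_nm[1L]]] else 0
    exp(b + g * log(t_years))
  }
  gm <- exp(mean(log(df$.time[df$.event == 1])))
  hr_table <- do.call(rbind, lapply(covariates, function(cv)
    data.frame(covariate = cv,
               hr_1y = hr_at(cv, 1), hr_2y = hr_at(cv, 2),
               hr_3y = hr_at(cv, 3), hr_gm = hr_at(cv, gm))))
  structure(list(fit = fit, hr_at = hr_at, geometric_mean_years = gm,
                 hr_table = hr_table, used = used),
            class = "tv_ph_fit")
}

#' Kaplan-Meier curves per group
#'
#' Product-limit survival estimates with Greenwood standard errors.
#'
#' @param times,events survival data
#' @param group group labels (e.g. subtype x arm)
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `survival`, `std_err`, `lower`, `upper`
#' @export
km_curve <- function(times, events, group = rep("all", length(times))) {
  df <- data.frame(.time = times, .event = events, group = factor(group))
  sf <- survival::survfit(survival::Surv(.time, .event) ~ group, data = df,
                          conf.type = "log")
  strata <- if (is.null(sf$strata)) rep(levels(df$group)[1L], length(sf$time))
            else rep(sub("^group=", "", names(sf$strata)), sf$strata)
  data.frame(group = strata, time = sf$time, n_risk = sf$n.risk,
             n_event = sf$n.event, survival = sf$surv,
             std_err = sf$std.err * sf$surv,   # Greenwood SE on survival scale
             lower = sf$lower, upper = sf$upper)
}

#' Subtype-by-arm outcome summary table
#'
#' Builds the per-subtype report: subjects per arm, cumulative and
#' one-year mortality and LVEF response percentages per arm, the
#' within-subtype treatment hazard ratio (Cox, Efron ties) and odds ratios
#' (2x2 cross-product with Woolf CIs), plus a totals row.  Ratio columns
#' are `NA` when only one arm is present.
#'
#' @param subtype per-subject subtype labels
#' @param outcomes data.frame with `treatment`, `followup_days`, `death`,
#'   `death_1y`, `lvef_response`
#' @param prefix subtype label prefix in the report (e.g. `"A"`)
#' @return data.frame shaped like the published outcome table
#' @export
subtype_outcome_table <- function(subtype, outcomes, prefix = "") {
  stopifnot(length(subtype) == nrow(outcomes))
  groups <- c(sort(unique(subtype)), "All")
  rows <- lapply(groups, function(s) {
    sel <- if (identical(s, "All")) rep(TRUE, nrow(outcomes))
           else subtype == s
    oc <- outcomes[sel, , drop = FALSE]
    plac <- oc$treatment == "placebo"
    pct <- function(x, g) if (!sum(g)) NA_real_
                          else 100 * mean(x[g], na.rm = TRUE)
    row <- data.frame(
      subtype = if (identical(s, "All")) "All" else paste0(prefix, s),
      n_plac = sum(plac), n_buc = sum(!plac),
      cum_mort_plac = pct(oc$death, plac),
      cum_mort_buc = pct(oc$death, !plac),
      hr = NA_real_, hr_lower = NA_real_, hr_upper = NA_real_,
      hr_p = NA_real_,
      mort1y_plac = pct(oc$death_1y, plac),
      mort1y_buc = pct(oc$death_1y, !plac),
      or_mort1y = NA_real_, or_mort1y_lower = NA_real_,
      or_mort1y_upper = NA_real_, or_mort1y_p = NA_real_,
      resp_plac = pct(oc$lvef_response, plac),
      resp_buc = pct(oc$lvef_response, !plac),
      or_resp = NA_real_, or_resp_lower = NA_real_,
      or_resp_upper = NA_real_, or_resp_p = NA_real_)
    if (sum(plac) > 0 && sum(!plac) > 0) {
      if (sum(oc$death) > 0) {
        ph <- fit_ph_model(oc$followup_days, oc$death, oc)
        z <- stats::qnorm(0.975)
        b <- stats::coef(ph$fit)[["treatment"]]
        se <- sqrt(stats::vcov(ph$fit)[1L, 1L])
        row$hr <- exp(b); row$hr_lower <- exp(b - z * se)
        row$hr_upper <- exp(b + z * se)
        row$hr_p <- 2 * stats::pnorm(-abs(b / se))
      }
      or_fill <- function(x) {
        ok <- !is.na(x)
        e <- tryCatch(two_by_two_odds_ratio(
          sum(x[!plac & ok]), sum(!x[!plac & ok]),
          sum(x[plac & ok]), sum(!x[plac & ok])), error = function(e) NULL)
        if (is.null(e)) rep(NA_real_, 4L)
        else c(e$estimate, e$lower, e$upper, e$p)
      }
      row[c("or_mort1y", "or_mort1y_lower", "or_mort1y_upper",
            "or_mort1y_p")] <- as.list(or_fill(oc$death_1y == 1L))
      row[c("or_resp", "or_resp_lower", "or_resp_upper", "or_resp_p")] <-
        as.list(or_fill(oc$lvef_response == 1L))
    }
    row
  })
  do.call(rbind, rows)
}
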