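#' Default generator parameters for a BEST-like synthetic cohort
#'
#' Returns the stated world the generator emulates: a 6-class structure for
#' the pathogenesis model (LCM A) and a 5-class structure for the
#' progression/severity model (LCM B), with class prevalences and
#' class-conditional category frequencies transcribed from the published
#' within-subtype percentage profiles of the BEST nonischemic HFREF cohort
#' (renormalised to probability simplexes), class- and arm-specific outcome
#' rates (cumulative mortality, one-year mortality, LVEF response)
#' transcribed from the published outcome table, n = 1121 with 563 placebo
#' / 558 bucindolol allocation, administrative censoring uniform on 2-4
#' years, and a 3-year horizon anchoring the cumulative mortality rate.
#'
#' @return an object of class `generator_params`
#' @export
default_params <- function() {
  norm_cols <- function(m) apply(m, 2L, renorm_pct)
  cond <- function(tbl) lapply(tbl, function(m) {
    if (nrow(m) == 1L) m <- rbind(m, 100 - m)   # binary rows print P(present)
    norm_cols(m)
  })
  a_rates <- .subtype_outcomes[.subtype_outcomes$lcm == "A", ]
  b_rates <- .subtype_outcomes[.subtype_outcomes$lcm == "B", ]
  structure(list(
    lcm_a = list(K = 6L,
                 prevalence = renorm_pct(.lcm_a_prevalence_pct),
                 conditionals = cond(.lcm_a_conditionals_pct)),
    lcm_b = list(K = 5L,
                 prevalence = renorm_pct(.lcm_b_prevalence_pct),
                 conditionals = cond(.lcm_b_conditionals_pct)),
    outcome_rates = list(A = a_rates, B = b_rates),
    outcome_lcm = "A",
    n = 1121L,
    n_placebo = 563L,
    censor_window_years = c(2, 4),
    cum_horizon_years = 3), class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  cat(sprintf("<generator_params> n = %d (%d placebo), LCM A: %d classes, LCM B: %d classes\n",
              x$n, x$n_placebo, x$lcm_a$K, x$lcm_b$K))
  invisible(x)
}

## draw 1-based categories from a per-class probability table (L x K)
draw_categories <- function(class, probs) {
  n <- length(class)
  out <- integer(n)
  for (k in seq_len(ncol(probs))) {
    idx <- which(class == k)
    if (length(idx))
      out[idx] <- sample.int(nrow(probs), length(idx), replace = TRUE,
                             prob = probs[, k])
  }
  out
}

## decode drawn category indices for one variable into raw cohort columns
decode_to_raw <- function(idx, var) {
  switch(var$kind,
    binned = stats::setNames(list(decode_level(idx, var)), var$columns),
    nominal = stats::setNames(list(var$levels[idx]), var$columns),
    binary = stats::setNames(list(ifelse(idx == 1L, 1L, 0L)), var$columns),
    composite_bp = {
      m <- decode_level(idx, var)
      stats::setNames(list(m[, 1L], m[, 2L]), var$columns)
    })
}

#' Generate raw clinical features with known latent structure
#'
#' Draws a latent class for each subject from the prevalence vector, then
#' draws every variable independently given class (the local-independence
#' assumption of the latent class model itself) and decodes category
#' indices to raw values: bin midpoints for binned variables (open-ended
#' bins sit 10% of the adjacent bin width beyond the edge), labels for
#' nominal variables, 0/1 for flags.  Re-encoding the raw table with the
#' codebook therefore reproduces the generated indices exactly.
#'
#' With `which = "both"`, LCM A and LCM B classes are drawn independently.
#' The three shared variables (BMI, creatinine clearance, hematocrit) take
#' their values from the LCM A draw, and systolic/pulse pressure derive
#' from the LCM A blood-pressure composite, so the B-side response matrix
#' is faithful to the B draw for the remaining variables only.
#'
#' @param params a [default_params()] object
#' @param n cohort size
#' @param seed RNG seed
#' @param which `"A"`, `"B"`, or `"both"`
#' @param cb codebook used for decoding
#' @return list with `data` (raw feature data.frame), `class_a`/`class_b`
#'   (true labels, `NULL` when not drawn), and `indices_a`/`indices_b`
#'   (generated category matrices)
#' @export
generate_features <- function(params, n = params$n, seed = 1L,
                              which = c("both", "A", "B"),
                              cb = default_codebook()) {
  which <- match.arg(which)
  set.seed(seed)
  out <- list(data = data.frame(subject_id = seq_len(n)),
              class_a = NULL, class_b = NULL,
              indices_a = NULL, indices_b = NULL)
  draw_side <- function(side) {
    spec <- if (side == "A") params$lcm_a else params$lcm_b
    vars <- if (side == "A") cb$lcm_a_vars else cb$lcm_b_vars
    class <- sample.int(spec$K, n, replace = TRUE, prob = spec$prevalence)
    idx <- sapply(seq_along(vars), function(j)
      draw_categories(class, spec$conditionals[[j]]))
    colnames(idx) <- vars
    list(class = class, idx = idx, vars = vars)
  }
  add_raw <- function(idx, vars, skip = character()) {
    for (nm in setdiff(vars, skip)) {
      cols <- decode_to_raw(idx[, nm], cb$variables[[nm]])
      for (cn in names(cols)) out$data[[cn]] <<- cols[[cn]]
    }
  }
  if (which %in% c("A", "both")) {
    a <- draw_side("A")
    out$class_a <- a$class; out$indices_a <- a$idx
    add_raw(a$idx, a$vars)
  }
  if (which %in% c("B", "both")) {
    b <- draw_side("B")
    out$class_b <- b$class; out$indices_b <- b$idx
    skip <- if (which == "both")
      c("bmi", "creatinine_clearance", "hematocrit", "systolic_bp",
        "pulse_pressure") else character()
    add_raw(b$idx, b$vars, skip)
    if (which == "B") {
      # diastolic pressure consistent with drawn systolic and pulse pressure
      out$data$dbp_mmhg <- out$data$sbp_mmhg - out$data$pulse_pressure_mmhg
    }
  }
  if (which == "both")
    out$data$pulse_pressure_mmhg <- out$data$sbp_mmhg - out$data$dbp_mmhg
  out
}

## piecewise-exponential hazard solved so that P(T <= 1y) = p1 and
## P(T <= horizon) = pcum; the late hazard continues beyond the horizon
solve_piecewise_hazard <- function(p1, pcum, horizon) {
  if (pcum < p1 - 1e-12)
    stopf("cumulative mortality (%.3f) below one-year mortality (%.3f)",
          pcum, p1)
  r1 <- -log(1 - p1)
  r2 <- max(0, (-log(1 - pcum) - r1) / (horizon - 1))
  c(r1 = r1, r2 = r2)
}

#' Simulate survival and LVEF-response outcomes
#'
#' Death times are piecewise exponential per class x arm: the hazard on
#' `[0, 1y]` matches the configured one-year mortality and the hazard on
#' `(1y, horizon]` matches the cumulative mortality at the horizon (and
#' continues beyond it).  Administrative censoring is uniform on the
#' configured window, which starts after one year so one-year vital status
#' is always observed.  LVEF response is Bernoulli with the class x arm
#' rate, independent of survival given class and arm (only marginal rates
#' are available); baseline and month-12 LVEF values are constructed to
#' satisfy or violate the response definition accordingly.
#'
#' @param class true latent class per subject (for `params$outcome_lcm`)
#' @param arm character vector, `"placebo"` / `"bucindolol"`
#' @param params a [default_params()] object
#' @param seed RNG seed
#' @param lcm which outcome-rate table to use (`"A"` or `"B"`)
#' @param lvef_baseline optional baseline LVEF (%) per subject
#' @return data.frame with `followup_days`, `death`, `death_1y`,
#'   `lvef_response`, `lvef_baseline_pct`, `lvef_month12_pct`
#' @export
simulate_outcomes <- function(class, arm, params, seed = 1L,
                              lcm = params$outcome_lcm,
                              lvef_baseline = NULL) {
  stopifnot(length(class) == length(arm))
  rates <- params$outcome_rates[[lcm]]
  if (max(class) > nrow(rates)) stopf("class label beyond the rate table")
  set.seed(seed)
  n <- length(class)
  horizon <- params$cum_horizon_years
  death_t <- numeric(n)
  resp <- integer(n)
  for (k in seq_len(nrow(rates))) for (a in c("plac", "buc")) {
    idx <- which(class == k &
                 arm == if (a == "plac") "placebo" else "bucindolol")
    if (!length(idx)) next
    p1 <- rates[[paste0("mort1y_", a)]][k] / 100
    pc <- rates[[paste0("cum_mort_", a)]][k] / 100
    rz <- solve_piecewise_hazard(p1, pc, horizon)
    e <- stats::rexp(length(idx))
    death_t[idx] <- ifelse(e < rz["r1"], e / rz["r1"],
                           if (rz["r2"] > 0) 1 + (e - rz["r1"]) / rz["r2"]
                           else Inf)
    resp[idx] <- stats::rbinom(length(idx), 1L,
                               rates[[paste0("resp_", a)]][k] / 100)
  }
  censor <- stats::runif(n, params$censor_window_years[1L],
                         params$censor_window_years[2L])
  time <- pmin(death_t, censor)
  death <- as.integer(death_t <= censor)
  if (is.null(lvef_baseline))
    lvef_baseline <- stats::runif(n, 15, 34.9)
  month12 <- ifelse(resp == 1L,
                    pmax(lvef_baseline + 5, 35) + stats::runif(n, 0, 8),
                    lvef_baseline + stats::runif(n, -8, 4.9))
  data.frame(followup_days = time * 365.25,
             death = death,
             death_1y = as.integer(death_t <= 1),
             lvef_response = resp,
             lvef_baseline_pct = lvef_baseline,
             lvef_month12_pct = month12)
}

#' Generate a complete BEST-like synthetic cohort
#'
#' Combines [generate_features()], randomised arm allocation, and
#' [simulate_outcomes()] into one patient-level table that satisfies the
#' cohort CSV schema expected by [encode_cohort()] and the outcome models.
#'
#' @inheritParams generate_features
#' @return an object of class `synthetic_cohort`: a data.frame of raw
#'   features, arm and outcomes, with true class labels in columns
#'   `class_a`/`class_b` and attributes `indices_a`/`indices_b`
#' @export
generate_cohort <- function(params = default_params(), n = params$n,
                            seed = 1L, which = "both",
                            cb = default_codebook()) {
  feat <- generate_features(params, n, seed = seed, which = which, cb = cb)
  set.seed(seed + 1L)
  n_plac <- round_half_up(n * params$n_placebo / params$n)
  arm <- sample(c(rep("placebo", n_plac), rep("bucindolol", n - n_plac)))
  lcm <- if (which == "B") "B" else "A"
  class_out <- if (lcm == "A") feat$class_a else feat$class_b
  out <- simulate_outcomes(class_out, arm, params, seed = seed + 2L,
                           lcm = lcm,
                           lvef_baseline = feat$data$lvef_pct)
  df <- cbind(feat$data, treatment = arm, out)
  if (!is.null(feat$class_a)) df$class_a <- feat$class_a
  if (!is.null(feat$class_b)) df$class_b <- feat$class_b
  structure(df, indices_a = feat$indices_a, indices_b = feat$indices_b,
            which = which, class = c("synthetic_cohort", "data.frame"))
}

#' Write / read a cohort CSV
#'
#' Numeric columns are serialised with 17 significant digits so the
#' write -> read round trip reproduces every value exactly.
#'
#' @param cohort data.frame
#' @param path file path
#' @export
write_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (nm in names(df)) {
    if (is.double(df[[nm]]))   # '#' keeps the decimal point so the value
      df[[nm]] <- sprintf("%#.17g", df[[nm]])   # reads back as double
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @return `read_cohort` returns the cohort data.frame
#' @export
read_cohort <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stopf("malformed cohort CSV '%s': %s", path,
                              conditionMessage(e)))
  df
}
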