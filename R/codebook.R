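#' Variable definition for the clinical codebook
#'
#' A `variable_def` describes how one raw clinical feature is discretised
#' into ordered categorical levels.  Four kinds are supported:
#'
#' * `"binned"`: a numeric feature cut at `bin_edges`.  Intervals are
#'   lower-closed / upper-open, with the final interval closed above by
#'   +Inf, so a value sitting exactly on a shared edge falls into the bin
#'   where it is the lower edge (BMI 25 encodes as "25-30").  `orientation`
#'   records whether the printed level order runs low-to-high
#'   (`"ascending"`, edges increasing) or high-to-low (`"descending"`,
#'   edges decreasing, e.g. hematocrit ">40" first).
#' * `"nominal"`: a labelled feature (race, diabetes grade, jugular venous
#'   distension); levels are matched by label.
#' * `"binary"`: a present/absent flag stored as 0/1 (or logical); absence
#'   of a record means absent.
#' * `"composite_bp"`: the blood-pressure staging composite.  Systolic and
#'   diastolic pressures are binned separately and the assigned category is
#'   the maximum of the two component bins, so either component can
#'   escalate the stage.
#'
#' @param name identifier used in codebooks and fitted models
#' @param kind one of `"binned"`, `"nominal"`, `"binary"`, `"composite_bp"`
#' @param levels ordered character vector of category labels (>= 2)
#' @param columns raw cohort column(s) this variable reads
#' @param bin_edges numeric cut points (binned variables only)
#' @param units free-text units of the raw measurement
#' @param orientation `"ascending"` or `"descending"` (binned only)
#' @param dbp_edges diastolic cut points (composite blood pressure only)
#' @return an object of class `variable_def`
#' @export
variable_def <- function(name, kind, levels, columns,
                         bin_edges = NULL, units = "",
                         orientation = "ascending", dbp_edges = NULL) {
  kind <- match.arg(kind, c("binned", "nominal", "binary", "composite_bp"))
  if (length(levels) < 2L) stopf("variable '%s' needs >= 2 levels", name)
  if (kind == "binned") {
    if (is.null(bin_edges)) stopf("variable '%s': binned without bin_edges", name)
    asc <- if (orientation == "ascending") bin_edges else rev(bin_edges)
    if (any(diff(asc) <= 0)) stopf("variable '%s': bin_edges not monotone", name)
    if (length(levels) != length(bin_edges) + 1L)
      stopf("variable '%s': need one more level than edges", name)
  }
  structure(list(name = name, kind = kind, levels = levels,
                 columns = columns, bin_edges = bin_edges, units = units,
                 orientation = orientation, dbp_edges = dbp_edges),
            class = "variable_def")
}

#' @export
print.variable_def <- function(x, ...) {
  cat(sprintf("<variable_def> %s [%s%s]: %s\n", x$name, x$kind,
              if (nzchar(x$units)) paste0(", ", x$units) else "",
              paste(x$levels, collapse = " | ")))
  invisible(x)
}

n_levels <- function(v) length(v$levels)

#' Construct a codebook
#'
#' @param variables named list of [variable_def()] objects
#' @param lcm_a_vars,lcm_b_vars variable names making up the two latent
#'   class models
#' @return an object of class `codebook`
#' @export
codebook <- function(variables, lcm_a_vars, lcm_b_vars) {
  nm <- vapply(variables, `[[`, "", "name")
  names(variables) <- nm
  miss <- setdiff(c(lcm_a_vars, lcm_b_vars), nm)
  if (length(miss)) stopf("codebook: undefined variables: %s",
                          paste(miss, collapse = ", "))
  structure(list(variables = variables,
                 lcm_a_vars = lcm_a_vars, lcm_b_vars = lcm_b_vars),
            class = "codebook")
}

#' @export
print.codebook <- function(x, ...) {
  cat(sprintf("<codebook> %d variables; LCM A: %d, LCM B: %d, shared: %d\n",
              length(x$variables), length(x$lcm_a_vars), length(x$lcm_b_vars),
              length(intersect(x$lcm_a_vars, x$lcm_b_vars))))
  invisible(x)
}

#' The default 27-feature HFREF codebook
#'
#' Returns the discretisation scheme for the 27 clinical features used to
#' phenotype nonischemic HFREF patients, partitioned into a
#' pathogenesis-oriented variable set (LCM A, 16 variables: age of heart
#' failure onset, sex, race, body mass index, diabetes grade, blood
#' pressure stage, total cholesterol, triglycerides, creatinine clearance,
#' hematocrit, and six history/ECG/valve flags) and a progression/severity
#' set (LCM B, 14 variables: age, LVEF, RVEF, QRS duration, heart rate,
#' systolic blood pressure, pulse pressure, jugular venous distension,
#' blood urea nitrogen, alanine aminotransferase, serum sodium, plus the
#' three shared variables).  Body mass index, creatinine clearance and
#' hematocrit appear in both sets.
#'
#' @return a [codebook()] with 27 variables
#' @export
default_codebook <- function() {
  v <- list(
    variable_def("hf_onset_age", "binned", c("<30", "30-45", "45-60", ">60"),
                 "hf_onset_age_years", c(30, 45, 60), "years"),
    variable_def("sex", "nominal", c("male", "female"), "sex"),
    variable_def("race", "nominal",
                 c("white", "black", "hispanic", "asian_pacific",
                   "american_indian", "other"), "race"),
    variable_def("bmi", "binned", c("<18.5", "18.5-25", "25-30", ">30"),
                 "bmi_kg_m2", c(18.5, 25, 30), "kg/m^2"),
    variable_def("diabetes", "nominal", c("none", "present", "end_organ"),
                 "diabetes"),
    variable_def("blood_pressure", "composite_bp",
                 c("<120/80", "120-140/80-90", "140-160/90-100", ">160/100"),
                 c("sbp_mmhg", "dbp_mmhg"), c(120, 140, 160), "mm Hg",
                 dbp_edges = c(80, 90, 100)),
    variable_def("total_cholesterol", "binned", c("<200", "200-240", ">240"),
                 "total_cholesterol_mg_dl", c(200, 240), "mg/dL"),
    variable_def("triglycerides", "binned", c("<150", "150-250", ">250"),
                 "triglycerides_mg_dl", c(150, 250), "mg/dL"),
    variable_def("creatinine_clearance", "binned",
                 c(">90", "60-90", "30-60", "15-30", "<15"),
                 "creatinine_clearance_ml_min", c(90, 60, 30, 15),
                 "ml/min.1.73m^2", orientation = "descending"),
    variable_def("hematocrit", "binned", c(">40", "30-40", "20-30", "<20"),
                 "hematocrit_pct", c(40, 30, 20), "%",
                 orientation = "descending"),
    variable_def("atrial_fibrillation", "binary", c("present", "absent"),
                 "afib"),
    variable_def("lbbb", "binary", c("present", "absent"), "lbbb"),
    variable_def("pacemaker", "binary", c("present", "absent"), "pacemaker"),
    variable_def("mitral_valve_disease", "binary", c("present", "absent"),
                 "mitral_valve_disease"),
    variable_def("aortic_valve_disease", "binary", c("present", "absent"),
                 "aortic_valve_disease"),
    variable_def("sudden_death_history", "binary", c("present", "absent"),
                 "sudden_death_history"),
    variable_def("age", "binned", c("<30", "30-45", "45-60", ">60"),
                 "age_years", c(30, 45, 60), "years"),
    variable_def("lvef", "binned", c(">55", "45-55", "35-45", "25-35", "<25"),
                 "lvef_pct", c(55, 45, 35, 25), "%",
                 orientation = "descending"),
    variable_def("rvef", "binned", c(">55", "45-55", "35-45", "25-35", "<25"),
                 "rvef_pct", c(55, 45, 35, 25), "%",
                 orientation = "descending"),
    variable_def("qrs", "binned", c("<120", "120-150", ">150"),
                 "qrs_msec", c(120, 150), "msec"),
    variable_def("heart_rate", "binned",
                 c("<60", "60-80", "80-100", "100-120", ">120"),
                 "heart_rate_bpm", c(60, 80, 100, 120), "bpm"),
    variable_def("systolic_bp", "binned",
                 c(">120", "110-120", "100-110", "90-100", "<90"),
                 "sbp_mmhg", c(120, 110, 100, 90), "mm Hg",
                 orientation = "descending"),
    variable_def("pulse_pressure", "binned", c(">40", "25-40", "<25"),
                 "pulse_pressure_mmhg", c(40, 25), "mm Hg",
                 orientation = "descending"),
    variable_def("jvd", "nominal",
                 c("none", "base_of_neck", "halfway_up", "angle_of_mandible"),
                 "jvd"),
    variable_def("bun", "binned", c("<10", "10-25", "25-40", "40-55", ">55"),
                 "bun_mg_dl", c(10, 25, 40, 55), "mg/dL"),
    variable_def("alt", "binned", c("<25", "25-50", "50-75", ">75"),
                 "alt_u_l", c(25, 50, 75), "U/L"),
    variable_def("sodium", "binned", c(">140", "130-140", "<130"),
                 "sodium_meq_l", c(140, 130), "mEq/L",
                 orientation = "descending")
  )
  codebook(
    v,
    lcm_a_vars = c("hf_onset_age", "sex", "race", "bmi", "diabetes",
                   "blood_pressure", "total_cholesterol", "triglycerides",
                   "creatinine_clearance", "hematocrit",
                   "atrial_fibrillation", "lbbb", "pacemaker",
                   "mitral_valve_disease", "aortic_valve_disease",
                   "sudden_death_history"),
    lcm_b_vars = c("age", "lvef", "rvef", "qrs", "heart_rate", "systolic_bp",
                   "pulse_pressure", "jvd", "bun", "alt", "sodium",
                   "bmi", "creatinine_clearance", "hematocrit")
  )
}

## map numeric values onto bins under the lower-closed convention
bin_index <- function(x, edges, orientation = "ascending") {
  if (orientation == "ascending") {
    findInterval(x, edges) + 1L
  } else {
    (length(edges) + 1L) - findInterval(x, rev(edges))
  }
}

#' Encode a raw value as a 1-based category index
#'
#' @param raw numeric value (binned/composite), label (nominal), or 0/1
#'   flag (binary); vectors are accepted.  For the composite blood-pressure
#'   variable supply a two-column matrix/data.frame (systolic, diastolic).
#' @param var a [variable_def()]
#' @return integer category indices; `NA` input gives `NA`
#' @export
encode_value <- function(raw, var) {
  switch(var$kind,
    binned = {
      if (!is.numeric(raw)) stopf("variable '%s': expected numeric", var$name)
      idx <- bin_index(raw, var$bin_edges, var$orientation)
      idx[is.na(raw)] <- NA_integer_
      idx
    },
    nominal = {
      raw <- as.character(raw)
      idx <- match(raw, var$levels)
      bad <- !is.na(raw) & is.na(idx)
      if (any(bad))
        stopf("variable '%s': unrecognised label(s): %s", var$name,
              paste(unique(raw[bad]), collapse = ", "))
      idx
    },
    binary = {
      x <- if (is.logical(raw)) as.integer(raw) else as.integer(raw)
      bad <- !is.na(x) & !(x %in% c(0L, 1L))
      if (any(bad)) stopf("variable '%s': flags must be 0/1", var$name)
      ifelse(is.na(x), NA_integer_, ifelse(x == 1L, 1L, 2L))
    },
    composite_bp = {
      m <- as.matrix(raw)
      if (ncol(m) != 2L)
        stopf("variable '%s': supply systolic and diastolic columns", var$name)
      sbp <- bin_index(m[, 1L], var$bin_edges, "ascending")
      dbp <- bin_index(m[, 2L], var$dbp_edges, "ascending")
      idx <- pmax(sbp, dbp)
      idx[is.na(m[, 1L]) | is.na(m[, 2L])] <- NA_integer_
      idx
    })
}

## decode a category index back to a representative raw value; open-ended
## bins sit 10% of the adjacent bin width beyond the edge so that every
## decoded value re-encodes to the generating category
decode_level <- function(idx, var) {
  stopifnot(var$kind %in% c("binned", "composite_bp"))
  decode_edges <- function(edges) {
    asc <- sort(edges)
    L <- length(asc) + 1L
    w1 <- asc[2L] - asc[1L]
    wL <- asc[L - 1L] - asc[L - 2L]
    mids <- c(asc[1L] - 0.1 * w1,
              if (L > 2L) (asc[-(L - 1L)] + asc[-1L]) / 2,
              asc[L - 1L] + 0.1 * wL)
    mids
  }
  if (var$kind == "binned") {
    asc_mids <- decode_edges(var$bin_edges)
    pos <- if (var$orientation == "ascending") idx else (n_levels(var) + 1L - idx)
    asc_mids[pos]
  } else {
    cbind(sbp = decode_edges(var$bin_edges)[idx],
          dbp = decode_edges(var$dbp_edges)[idx])
  }
}

#' Encode a cohort into a categorical response matrix
#'
#' Applies the codebook to the raw cohort columns of the selected latent
#' class model and returns a `response_matrix`: an `n x J` integer matrix
#' of 1-based category indices plus a missingness mask.  Subjects missing
#' any required raw value keep `NA` entries and are flagged; downstream
#' latent class fitting uses listwise deletion.
#'
#' @param cohort data.frame of raw patient-level features
#' @param cb a [codebook()]; defaults to [default_codebook()]
#' @param which `"A"` or `"B"`, selecting the LCM variable set
#' @return an object of class `response_matrix`
#' @export
encode_cohort <- function(cohort, cb = default_codebook(),
                          which = c("A", "B")) {
  which <- match.arg(which)
  vars <- if (which == "A") cb$lcm_a_vars else cb$lcm_b_vars
  need <- unlist(lapply(cb$variables[vars], `[[`, "columns"))
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stopf("cohort is missing required column(s): %s",
          paste(miss, collapse = ", "))
  n <- nrow(cohort)
  values <- matrix(NA_integer_, n, length(vars),
                   dimnames = list(NULL, vars))
  for (nm in vars) {
    v <- cb$variables[[nm]]
    raw <- if (v$kind == "composite_bp") cohort[v$columns] else cohort[[v$columns]]
    values[, nm] <- encode_value(raw, v)
  }
  structure(list(values = values,
                 variable_names = vars,
                 n_levels = vapply(cb$variables[vars], n_levels, 1L),
                 missing = is.na(values),
                 which = which),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> LCM %s: %d subjects x %d variables (%d complete)\n",
              x$which, nrow(x$values), ncol(x$values),
              sum(rowSums(x$missing) == 0L)))
  invisible(x)
}

#' Size of the categorical response-pattern space
#'
#' The number of distinct complete response patterns for a latent class
#' model's variable set, i.e. the product of the level counts.  This is the
#' number of cells a fully saturated interaction model would need, which is
#' why latent class aggregation is required at realistic sample sizes.
#'
#' @inheritParams encode_cohort
#' @return exact integer (as double when beyond `.Machine$integer.max`)
#' @export
pattern_space_size <- function(cb = default_codebook(), which = c("A", "B")) {
  which <- match.arg(which)
  vars <- if (which == "A") cb$lcm_a_vars else cb$lcm_b_vars
  prod(vapply(cb$variables[vars], n_levels, 1L))
}

#' Write / read a codebook as editable JSON
#'
#' @param cb a [codebook()]
#' @param path file path
#' @return `read_codebook` returns the [codebook()]; `write_codebook`
#'   returns `path` invisibly
#' @export
write_codebook <- function(cb, path) {
  payload <- list(
    variables = lapply(unname(cb$variables), function(v)
      v[c("name", "kind", "levels", "columns", "bin_edges", "units",
          "orientation", "dbp_edges")]),
    lcm_a_vars = cb$lcm_a_vars,
    lcm_b_vars = cb$lcm_b_vars)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  vars <- lapply(raw$variables, function(v)
    variable_def(v$name, v$kind, unlist(v$levels), unlist(v$columns),
                 bin_edges = if (!is.null(v$bin_edges)) unlist(v$bin_edges),
                 units = v$units %||% "",
                 orientation = v$orientation %||% "ascending",
                 dbp_edges = if (!is.null(v$dbp_edges)) unlist(v$dbp_edges)))
  codebook(vars, unlist(raw$lcm_a_vars), unlist(raw$lcm_b_vars))
}
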