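#' Harrell's concordance index for censored survival data
#'
#' Over all usable pairs — pairs whose ordering of event times is known
#' under censoring, i.e. the earlier time is an observed event and the
#' times differ — counts the fraction in which the higher risk score
#' belongs to the earlier event; risk ties count 0.5.
#'
#' @param times follow-up times
#' @param events 0/1 event indicators
#' @param risk finite risk scores (higher = riskier)
#' @return concordance in `[0, 1]`
#' @export
harrell_c <- function(times, events, risk) {
  stopifnot(length(times) == length(events), length(times) == length(risk))
  if (any(!is.finite(risk))) stopf("risk scores must be finite")
  n <- length(times)
  ti <- matrix(times, n, n)
  ei <- matrix(events == 1, n, n)
  usable <- (ti < t(ti)) & ei            # i strictly earlier and an event
  if (!any(usable)) stopf("no usable pairs: concordance undefined")
  ri <- matrix(risk, n, n)
  conc <- sum(usable & (ri > t(ri))) + 0.5 * sum(usable & (ri == t(ri)))
  conc / sum(usable)
}

#' ROC area (c-statistic) for a binary outcome
#'
#' Mann-Whitney form: the probability that a random event outranks a
#' random non-event, ties counting 0.5.
#'
#' @param labels 0/1 outcome
#' @param probabilities predicted risks or any monotone score
#' @return AUC in `[0, 1]`
#' @export
binary_c <- function(labels, probabilities) {
  stopifnot(length(labels) == length(probabilities))
  lab <- as.integer(labels)
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0L || n0 == 0L)
    stopf("both outcome classes must be present")
  r <- rank(probabilities)
  (sum(r[lab == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## placement values of the DeLong construction: for each event, the
## fraction of non-events it outranks (and vice versa)
delong_placements <- function(probs, labels) {
  x <- probs[labels == 1L]
  y <- probs[labels == 0L]
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = 1 - colMeans(cmp), auc = mean(cmp))
}

#' Compare two correlated c-statistics (DeLong test)
#'
#' Tests equality of the ROC areas of two models evaluated on the same
#' subjects, using the DeLong covariance of the paired placement values;
#' the squared standardised difference is referred to chi-square with one
#' degree of freedom.  Identical prediction vectors give p = 1.
#'
#' @param probs1,probs2 paired predictions from the two models
#' @param labels shared 0/1 outcome
#' @return list: `auc1`, `auc2`, `difference`, `chisq`, `p`
#' @export
compare_c <- function(probs1, probs2, labels) {
  stopifnot(length(probs1) == length(probs2),
            length(probs1) == length(labels))
  lab <- as.integer(labels)
  pl1 <- delong_placements(probs1, lab)
  pl2 <- delong_placements(probs2, lab)
  d <- pl1$auc - pl2$auc
  if (isTRUE(all.equal(probs1, probs2, tolerance = 0)))
    return(list(auc1 = pl1$auc, auc2 = pl2$auc, difference = 0,
                chisq = 0, p = 1))
  m <- sum(lab == 1L); n0 <- sum(lab == 0L)
  s10 <- stats::cov(cbind(pl1$v10, pl2$v10))
  s01 <- stats::cov(cbind(pl1$v01, pl2$v01))
  S <- s10 / m + s01 / n0
  v <- S[1L, 1L] + S[2L, 2L] - 2 * S[1L, 2L]
  if (v <= 0) return(list(auc1 = pl1$auc, auc2 = pl2$auc, difference = d,
                          chisq = 0, p = 1))
  chisq <- d^2 / v
  list(auc1 = pl1$auc, auc2 = pl2$auc, difference = d, chisq = chisq,
       p = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

#' Net reclassification improvement
#'
#' Categorical NRI over configured risk categories — events:
#' `P(up) - P(down)`; non-events: `P(down) - P(up)`; overall = sum — with
#' the per-class transition matrices, plus the category-free (continuous)
#' NRI in which any increase counts as up-classification.
#'
#' @param old,new predicted risks in `[0, 1]` from the baseline and
#'   updated model
#' @param labels 0/1 outcome
#' @param thresholds strictly increasing risk-category cut points in
#'   (0, 1); `NULL` for category-free NRI only
#' @return list of class `nri_result`: `categorical` (components +
#'   `table_events` / `table_nonevents`), `continuous` (components)
#' @export
nri <- function(old, new, labels, thresholds = NULL) {
  stopifnot(length(old) == length(new), length(old) == length(labels))
  if (any(old < 0 | old > 1 | new < 0 | new > 1))
    stopf("risks must lie in [0, 1]")
  lab <- as.integer(labels)
  ev <- lab == 1L
  comp <- function(up, down) {
    list(event = mean(up[ev]) - mean(down[ev]),
         nonevent = mean(down[!ev]) - mean(up[!ev]))
  }
  continuous <- comp(new > old, new < old)
  continuous$overall <- continuous$event + continuous$nonevent
  categorical <- NULL
  if (!is.null(thresholds)) {
    if (any(diff(thresholds) <= 0))
      stopf("risk-category thresholds must be strictly increasing")
    cuts <- c(-Inf, thresholds, Inf)
    co <- cut(old, cuts, right = FALSE)
    cn <- cut(new, cuts, right = FALSE)
    categorical <- comp(as.integer(cn) > as.integer(co),
                        as.integer(cn) < as.integer(co))
    categorical$overall <- categorical$event + categorical$nonevent
    categorical$table_events <- table(old = co[ev], new = cn[ev])
    categorical$table_nonevents <- table(old = co[!ev], new = cn[!ev])
  }
  structure(list(categorical = categorical, continuous = continuous,
                 thresholds = thresholds), class = "nri_result")
}

#' @export
print.nri_result <- function(x, ...) {
  f <- function(l, nm) cat(sprintf(
    "  %s: events %+0.4f, non-events %+0.4f, overall %+0.4f\n",
    nm, l$event, l$nonevent, l$overall))
  cat("<nri_result>\n")
  if (!is.null(x$categorical))
    f(x$categorical, sprintf("categorical (cuts %s)",
                             paste(x$thresholds, collapse = "/")))
  f(x$continuous, "category-free")
  invisible(x)
}

## uncentred Cox linear predictor on new data, built from the stored terms
## and factor levels so it works outside the fitting environment
cox_lp <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit))
  mf <- stats::model.frame(tt, newdata, xlev = fit$xlevels,
                           na.action = stats::na.pass)
  X <- stats::model.matrix(tt, mf, contrasts.arg = fit$contrasts)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  drop(X %*% stats::coef(fit))
}

#' Leave-one-out cross-validated c-index
#'
#' For each subject the outcome regression is refit on the remaining
#' n - 1 subjects and the held-out subject is predicted; the c-index is
#' computed on the assembled out-of-fold predictions.  There is no
#' randomness: the result is a deterministic function of the data and the
#' model specification.  Covariates built upstream (subtype assignments,
#' SHFM scores) are frozen, matching the default evaluation scheme;
#' re-deriving them per fold is a pipeline-level option.
#'
#' @param formula model formula (for `type = "cox"` use
#'   `survival::Surv(time, event) ~ ...`)
#' @param data data.frame with all model variables
#' @param type `"binomial"` (logistic; c = ROC area on out-of-fold
#'   probabilities) or `"cox"` (partial likelihood; Harrell c on
#'   out-of-fold linear predictors)
#' @return list: `c` (cross-validated c-index), `apparent` (same-data
#'   c-index of the full fit), `predictions`, `failed_folds`
#' @export
loocv_c <- function(formula, data, type = c("binomial", "cox")) {
  type <- match.arg(type)
  n <- nrow(data)
  if (n < 20L) stopf("leave-one-out cross-validation needs n >= 20")
  pred <- rep(NA_real_, n)
  failed <- integer()
  predict_one <- function(train, test) {
    if (type == "binomial") {
      fit <- stats::glm(formula, stats::binomial(), data = train)
      unname(stats::predict(fit, newdata = test, type = "response"))
    } else {
      fit <- survival::coxph(formula, data = train, ties = "efron")
      unname(cox_lp(fit, test))
    }
  }
  for (i in seq_len(n)) {
    pred[i] <- tryCatch(
      predict_one(data[-i, , drop = FALSE], data[i, , drop = FALSE]),
      error = function(e) NA_real_)
    if (is.na(pred[i])) failed <- c(failed, i)
  }
  if (length(failed))
    warning(sprintf("%d LOOCV fold(s) failed and were excluded",
                    length(failed)), call. = FALSE)
  ok <- !is.na(pred)
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  apparent_pred <- predict_one(data, data)
  if (type == "binomial") {
    cv <- binary_c(y[ok], pred[ok])
    apparent <- binary_c(y, apparent_pred)
  } else {
    cv <- harrell_c(y[ok, 1L], y[ok, 2L], pred[ok])
    apparent <- harrell_c(y[, 1L], y[, 2L], apparent_pred)
  }
  list(c = cv, apparent = apparent, predictions = pred,
       failed_folds = failed)
}
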