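#' @useDynLib hfsubtype, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## coerce response input (response_matrix or plain integer matrix) to a
## complete-case integer matrix plus bookkeeping
as_response <- function(data, n_levels = NULL) {
  if (is.list(data) && !is.null(data$values)) {
    # response_matrix, or an already-normalised internal response list
    values <- data$values
    n_levels <- data$n_levels %||% n_levels
    vars <- data$variable_names
  } else {
    values <- as.matrix(data)
    storage.mode(values) <- "integer"
    vars <- colnames(values) %||% paste0("v", seq_len(ncol(values)))
    if (is.null(n_levels)) n_levels <- apply(values, 2L, max, na.rm = TRUE)
  }
  complete <- rowSums(is.na(values)) == 0L
  list(values = values[complete, , drop = FALSE],
       n_levels = as.integer(n_levels),
       variable_names = vars,
       n_total = nrow(values), n_used = sum(complete),
       complete = complete)
}

#' Construct a polytomous latent class model
#'
#' @param pi length-K class prevalences (simplex)
#' @param p list over variables of `L_j x K` class-conditional category
#'   probability matrices (each column a simplex)
#' @param variable_names names for the J variables
#' @return an object of class `lca_model`
#' @export
lca_model <- function(pi, p, variable_names = names(p)) {
  K <- length(pi)
  if (!is_prob_vector(pi)) stopf("pi must be a probability vector")
  for (j in seq_along(p)) {
    pj <- as.matrix(p[[j]])
    if (ncol(pj) != K) stopf("p[[%d]] must have K = %d columns", j, K)
    ok <- apply(pj, 2L, is_prob_vector)
    if (!all(ok)) stopf("p[[%d]]: columns must be probability simplexes", j)
    p[[j]] <- pj
  }
  if (is.null(variable_names))
    variable_names <- paste0("v", seq_along(p))
  names(p) <- variable_names
  structure(list(K = K, pi = as.numeric(pi), p = p,
                 n_levels = vapply(p, nrow, 1L),
                 variable_names = variable_names),
            class = "lca_model")
}

#' @export
print.lca_model <- function(x, ...) {
  cat(sprintf("<lca_model> K = %d classes, %d variables\n", x$K,
              length(x$p)))
  cat("  prevalences:", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

## reorder classes by descending prevalence (stable on ties); likelihood
## is invariant under this relabelling
relabel_by_prevalence <- function(model) {
  o <- order(model$pi, decreasing = TRUE)
  model$pi <- model$pi[o]
  model$p <- lapply(model$p, function(pj) pj[, o, drop = FALSE])
  model
}

check_model_data <- function(model, resp) {
  if (length(model$n_levels) != ncol(resp$values))
    stopf("model has %d variables but data has %d",
          length(model$n_levels), ncol(resp$values))
  mx <- apply(resp$values, 2L, max)
  if (any(mx > model$n_levels))
    stopf("data contains category indices beyond the model's level counts")
}

#' Log-likelihood of a latent class model
#'
#' Computes `sum_i log sum_k pi_k prod_j p[j][k][y_ij]` over the complete
#' cases of `data`.
#'
#' @param model an [lca_model()]
#' @param data a `response_matrix` or integer matrix of category indices
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(model, data) {
  resp <- as_response(data, model$n_levels)
  check_model_data(model, resp)
  .lca_estep_cpp(resp$values, model$pi, unname(model$p))$log_likelihood
}

#' E-step: posterior class-membership probabilities
#'
#' Row i, class k holds `pi_k prod_j p[j][k][y_ij]` normalised over k.
#'
#' @inheritParams log_likelihood
#' @return `n x K` posterior matrix with unit row sums
#' @export
e_step <- function(model, data) {
  resp <- as_response(data, model$n_levels)
  check_model_data(model, resp)
  .lca_estep_cpp(resp$values, model$pi, unname(model$p))$posterior
}

#' M-step: maximum-likelihood update given posteriors
#'
#' Prevalences become mean posteriors; conditionals become
#' posterior-weighted category frequencies.  A probability floor keeps
#' conditionals away from exact zero (renormalised afterwards).
#'
#' @param posterior `n x K` matrix with unit row sums
#' @param data response data (complete cases only)
#' @param n_levels level count per variable (defaults to observed maxima)
#' @param prob_floor lower bound on conditional probabilities
#' @return an [lca_model()]
#' @export
m_step <- function(posterior, data, n_levels = NULL, prob_floor = 1e-10) {
  resp <- as_response(data, n_levels)
  y <- resp$values
  n <- nrow(y)
  stopifnot(nrow(posterior) == n)
  cs <- colSums(posterior)
  if (any(cs <= 0)) stopf("degenerate class: zero posterior mass")
  pi <- cs / sum(cs)
  p <- lapply(seq_len(ncol(y)), function(j) {
    Lj <- resp$n_levels[j]
    ind <- matrix(0, n, Lj)
    ind[cbind(seq_len(n), y[, j])] <- 1
    m <- crossprod(ind, posterior)           # L_j x K weighted counts
    m <- sweep(m, 2L, cs, "/")
    m <- pmax(m, prob_floor)
    sweep(m, 2L, colSums(m), "/")
  })
  lca_model(pi, p, resp$variable_names)
}

#' Number of free parameters of a K-class polytomous LCA
#'
#' `(K - 1) + K * sum_j (L_j - 1)`: the prevalence simplex plus one
#' conditional simplex per class and variable.
#'
#' @param K class count
#' @param level_counts integer vector of category counts per variable
#' @return integer parameter count
#' @export
n_parameters <- function(K, level_counts) {
  stopifnot(K >= 1)
  as.integer((K - 1L) + K * sum(level_counts - 1L))
}

#' Fit a latent class model by multi-start EM
#'
#' Runs `n_starts` EM runs from random Dirichlet(1) posterior
#' initialisations and keeps the best log-likelihood solution.  Classes are
#' relabelled by descending prevalence.  The fit is deterministic given
#' `seed`.
#'
#' @inheritParams log_likelihood
#' @param K number of classes (>= 1)
#' @param n_starts random restarts
#' @param seed RNG seed (required for reproducibility)
#' @param tol relative log-likelihood convergence tolerance
#' @param max_iter maximum EM iterations per start
#' @param prob_floor conditional-probability floor inside the M-step
#' @return an object of class `lca_fit` with elements `model`,
#'   `log_likelihood`, `n_parameters`, `bic`, `chi_square`, `n_used`,
#'   `converged`, `trace`, `n_starts`, `seed`, `floor_hits`
#' @export
fit_lca <- function(data, K, n_starts = 20L, seed = 1L, tol = 1e-8,
                    max_iter = 5000L, prob_floor = 1e-10) {
  stopifnot(K >= 1)
  resp <- as_response(data)
  y <- resp$values
  n <- nrow(y)
  if (n < 1L) stopf("no complete cases to fit")
  npat <- nrow(unique(y))
  if (npat < K)
    stopf("only %d distinct complete response patterns for K = %d", npat, K)

  if (K == 1L) {
    ## closed form: no latent structure
    model <- m_step(matrix(1, n, 1L), resp, resp$n_levels, prob_floor)
    es <- .lca_estep_cpp(y, model$pi, unname(model$p))
    best <- list(model = model, log_likelihood = es$log_likelihood,
                 converged = TRUE, trace = es$log_likelihood,
                 floor_hits = 0L)
  } else {
    best <- NULL
    old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           envir = globalenv()))
    set.seed(seed)
    for (s in seq_len(n_starts)) {
      post0 <- rdirichlet1(n, K)
      init <- m_step(post0, resp, resp$n_levels, prob_floor)
      em <- .lca_em_cpp(y, init$pi, unname(init$p), tol, max_iter,
                        prob_floor)
      if (any(diff(em$trace) < -1e-6))
        stopf("EM log-likelihood decreased (internal error)")
      if (is.null(best) || em$log_likelihood > best$log_likelihood) {
        model <- lca_model(em$pi, em$p, resp$variable_names)
        best <- list(model = model, log_likelihood = em$log_likelihood,
                     converged = em$converged, trace = em$trace,
                     floor_hits = em$floor_hits)
      }
    }
  }
  model <- relabel_by_prevalence(best$model)
  phi <- n_parameters(K, resp$n_levels)
  fit <- structure(list(
    model = model,
    log_likelihood = best$log_likelihood,
    n_parameters = phi,
    bic = -2 * best$log_likelihood + phi * log(resp$n_used),
    n_used = resp$n_used,
    n_total = resp$n_total,
    converged = best$converged,
    trace = best$trace,
    n_starts = n_starts, seed = seed,
    floor_hits = best$floor_hits), class = "lca_fit")
  fit$chi_square <- chi_square_gof(fit, resp)
  fit
}

#' @export
print.lca_fit <- function(x, ...) {
  cat(sprintf(paste0("<lca_fit> K = %d, n = %d, logLik = %.2f, ",
                     "BIC = %.2f, chi^2 = %.1f, converged = %s\n"),
              x$model$K, x$n_used, x$log_likelihood, x$bic, x$chi_square,
              x$converged))
  invisible(x)
}

#' Pearson chi-square goodness of fit over response patterns
#'
#' Sums `(observed - expected)^2 / expected` over the observed response
#' patterns, with expected counts `n * P_model(pattern)`; the expected mass
#' of all unobserved patterns is aggregated into one residual cell (whose
#' observed count is zero, contributing exactly that mass).
#'
#' @param fit an `lca_fit` (or bare [lca_model()])
#' @param data the response data the model was fitted to
#' @return the Pearson statistic (non-negative)
#' @export
chi_square_gof <- function(fit, data) {
  model <- if (inherits(fit, "lca_fit")) fit$model else fit
  resp <- as_response(data, model$n_levels)
  y <- resp$values
  n <- nrow(y)
  key <- apply(y, 1L, paste, collapse = "\r")
  obs <- table(key)
  uy <- y[!duplicated(key), , drop = FALSE]
  ukey <- key[!duplicated(key)]
  ## mixture probability of each unique observed pattern
  lp <- matrix(rep(log(model$pi), each = nrow(uy)), nrow(uy), model$K)
  for (j in seq_len(ncol(uy)))
    lp <- lp + log(model$p[[j]])[uy[, j], , drop = FALSE]
  pr <- exp(row_logsumexp(lp))
  expd <- n * pr
  o <- as.numeric(obs[ukey])
  stat <- sum((o - expd)^2 / expd)
  rest <- n - sum(expd)           # expected mass on unobserved patterns
  if (rest > 0) stat <- stat + rest
  stat
}

## local-minimum scan used by the model-order rule: first index that is
## strictly below both neighbours, one-sided at the endpoints
first_local_min <- function(x) {
  n <- length(x)
  for (i in seq_len(n)) {
    left_ok <- i == 1L || x[i] < x[i - 1L]
    right_ok <- i == n || x[i] < x[i + 1L]
    if (left_ok && right_ok) return(i)
  }
  NA_integer_
}

#' Select the number of latent classes (BIC-then-chi-square rule)
#'
#' Fits every K in `K_range` and applies the two-stage rule: find the first
#' local minimum of BIC over K, then select the first K at or beyond it
#' that is a local minimum of the Pearson chi-square statistic (one-sided
#' comparisons at the range endpoints).  If a stage has no local minimum
#' the global minimum (over the admissible Ks) is used and flagged.
#'
#' @inheritParams fit_lca
#' @param K_range contiguous integer range of class counts, minimum >= 2
#' @param verbose print progress per K
#' @return an object of class `lcm_selection`: `selected_k`, `k_bic`,
#'   `diagnostics` (per-K table), `fallback_bic`, `fallback_chisq`, and
#'   `fit` (the fit at the selected K)
#' @export
select_num_classes <- function(data, K_range = 2:10, n_starts = 10L,
                               seed = 1L, tol = 1e-8, max_iter = 5000L,
                               verbose = FALSE) {
  K_range <- as.integer(K_range)
  stopifnot(min(K_range) >= 2L, all(diff(K_range) == 1L))
  resp <- as_response(data)
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    fits[[i]] <- fit_lca(resp, K_range[i], n_starts = n_starts,
                         seed = seed + K_range[i], tol = tol,
                         max_iter = max_iter)
    if (verbose)
      message(sprintf("K = %d: BIC = %.1f, chi^2 = %.1f", K_range[i],
                      fits[[i]]$bic, fits[[i]]$chi_square))
  }
  bic <- vapply(fits, `[[`, 0, "bic")
  chisq <- vapply(fits, `[[`, 0, "chi_square")
  diagnostics <- data.frame(
    K = K_range,
    log_likelihood = vapply(fits, `[[`, 0, "log_likelihood"),
    n_parameters = vapply(fits, `[[`, 0L, "n_parameters"),
    bic = bic, chi_square = chisq,
    converged = vapply(fits, `[[`, TRUE, "converged"))

  i_bic <- first_local_min(bic)
  fallback_bic <- is.na(i_bic)
  if (fallback_bic) i_bic <- which.min(bic)

  tail_idx <- seq.int(i_bic, length(K_range))
  i_chi_rel <- first_local_min(chisq[tail_idx])
  fallback_chisq <- is.na(i_chi_rel)
  i_chi <- if (fallback_chisq) tail_idx[which.min(chisq[tail_idx])]
           else tail_idx[i_chi_rel]

  structure(list(selected_k = K_range[i_chi],
                 k_bic = K_range[i_bic],
                 diagnostics = diagnostics,
                 fallback_bic = fallback_bic,
                 fallback_chisq = fallback_chisq,
                 fit = fits[[i_chi]]),
            class = "lcm_selection")
}

#' @export
print.lcm_selection <- function(x, ...) {
  cat(sprintf("<lcm_selection> selected K = %d (BIC stage: K = %d%s%s)\n",
              x$selected_k, x$k_bic,
              if (x$fallback_bic) ", BIC fallback" else "",
              if (x$fallback_chisq) ", chi^2 fallback" else ""))
  print(x$diagnostics, row.names = FALSE)
  invisible(x)
}

#' Bayesian subtype assignment under a frozen model
#'
#' Computes posterior class-membership probabilities for (new) subjects via
#' Bayes' rule on the fitted model, and hard labels by posterior argmax
#' (ties broken toward the lower class index).  All model variables must be
#' present: subjects with missing entries are rejected rather than assigned
#' from partial profiles.
#'
#' @param model an [lca_model()] or `lca_fit`
#' @param data encoded responses for the model's variable set
#' @return an object of class `subtype_assignment` with `posterior`
#'   (`n x K`) and `label` (integer vector)
#' @export
assign_subtype <- function(model, data) {
  if (inherits(model, "lca_fit")) model <- model$model
  resp <- as_response(data, model$n_levels)
  if (resp$n_used < resp$n_total) {
    bad <- which(!resp$complete)[1L]
    j <- which(is.na(if (inherits(data, "response_matrix")) data$values[bad, ]
                     else as.matrix(data)[bad, ]))[1L]
    stopf("subject %d is missing variable '%s'; cannot assign from a partial profile",
          bad, resp$variable_names[j])
  }
  check_model_data(model, resp)
  post <- e_step(model, resp)
  label <- apply(post, 1L, which.max)   # which.max: ties -> lowest index
  structure(list(posterior = post, label = as.integer(label), K = model$K),
            class = "subtype_assignment")
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("<subtype_assignment> %d subjects, K = %d\n",
              length(x$label), x$K))
  print(table(class = x$label))
  invisible(x)
}

#' Save / load a fitted latent class model as JSON
#'
#' Serialisation is full double precision, so write -> read round-trips
#' bit-exactly.
#'
#' @param fit an `lca_fit` or [lca_model()]
#' @param path file path
#' @export
write_lca_model <- function(fit, path) {
  model <- if (inherits(fit, "lca_fit")) fit$model else fit
  meta <- if (inherits(fit, "lca_fit"))
    fit[c("log_likelihood", "n_parameters", "bic", "chi_square", "n_used",
          "converged", "n_starts", "seed")] else NULL
  payload <- list(K = model$K, pi = model$pi,
                  p = lapply(unname(model$p), function(m)
                    apply(m, 2L, identity, simplify = FALSE)),
                  n_levels = unname(model$n_levels),
                  variable_names = model$variable_names,
                  meta = meta)
  # I(17) = 17 significant digits, enough for a bit-exact double round trip
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_lca_model
#' @return `read_lca_model` returns an [lca_model()]; fit metadata, when
#'   present, is attached as attribute `"meta"`
#' @export
read_lca_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  p <- lapply(raw$p, function(cols)
    do.call(cbind, lapply(cols, function(col) unlist(col, use.names = FALSE))))
  m <- lca_model(unlist(raw$pi), p,
                 unlist(raw$variable_names, use.names = FALSE))
  if (!is.null(raw$meta)) attr(m, "meta") <- lapply(raw$meta, unlist)
  m
}
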