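test_that("log-likelihood matches closed forms and the enumeration oracle", {
  m1 <- lca_model(1, list(matrix(c(0.5, 0.5), 2, 1)), "v1")
  expect_equal(log_likelihood(m1, matrix(1L, 1, 1)), log(0.5))

  # two identical classes collapse to the shared single-class likelihood
  pj <- cbind(c(0.3, 0.7), c(0.3, 0.7))
  m2 <- lca_model(c(0.5, 0.5), list(pj), "v1")
  y <- matrix(c(1L, 2L, 2L), 3, 1)
  expect_equal(log_likelihood(m2, y),
               log_likelihood(lca_model(1, list(pj[, 1, drop = FALSE])), y))

  set.seed(4)
  p <- list(cbind(c(0.8, 0.2), c(0.3, 0.7)),
            cbind(c(0.1, 0.5, 0.4), c(0.6, 0.2, 0.2)))
  m <- lca_model(c(0.4, 0.6), p)
  y <- cbind(c(1L, 2L, 1L), c(3L, 1L, 2L))
  expect_equal(log_likelihood(m, y), oracle_loglik(m$pi, m$p, y),
               tolerance = 1e-12)
})

test_that("e_step matches Bayes' rule", {
  y <- cbind(c(1L, 2L, 1L), c(3L, 1L, 2L))
  p <- list(cbind(c(0.8, 0.2), c(0.3, 0.7)),
            cbind(c(0.1, 0.5, 0.4), c(0.6, 0.2, 0.2)))
  m <- lca_model(c(0.4, 0.6), p)
  post <- e_step(m, y)
  expect_equal(post, oracle_posterior(m$pi, m$p, y), tolerance = 1e-12)
  expect_equal(rowSums(post), rep(1, 3))

  # K = 1: certainty; symmetric model + symmetric observation: 0.5/0.5
  m1 <- lca_model(1, list(matrix(c(0.5, 0.5), 2, 1)))
  expect_equal(e_step(m1, matrix(1L, 4, 1)), matrix(1, 4, 1))
  msym <- lca_model(c(0.5, 0.5), list(cbind(c(0.5, 0.5), c(0.5, 0.5))))
  expect_equal(e_step(msym, matrix(2L, 1, 1)), matrix(0.5, 1, 2))
})

test_that("m_step reduces to (weighted) counting and conserves simplexes", {
  y <- cbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 1L, 2L))
  hard <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  m <- m_step(hard, y)
  expect_equal(m$pi, c(0.5, 0.5))
  expect_equal(m$p[[1]][, 1], c(1, 0), tolerance = 1e-9)
  expect_equal(m$p[[2]][, 1], c(0.5, 0.5))

  unif <- matrix(0.5, 4, 2)
  mu <- m_step(unif, y)
  expect_equal(mu$p[[1]][, 1], mu$p[[1]][, 2])
  expect_equal(mu$p[[1]][, 1], c(0.5, 0.5))   # pooled marginal

  w <- rbind(c(0.9, 0.1), c(0.6, 0.4), c(0.2, 0.8), c(0.3, 0.7))
  mw <- m_step(w, y)
  cs <- colSums(w)
  expect_equal(mw$pi, cs / 4)
  expect_equal(mw$p[[1]][1, 1], (0.9 + 0.6) / cs[1], tolerance = 1e-9,
               ignore_attr = TRUE)
  for (j in 1:2)
    expect_equal(colSums(mw$p[[j]]), c(1, 1), tolerance = 1e-10)
  expect_error(m_step(matrix(c(1, 0, 1, 0), 2, 2, byrow = TRUE) * 0 +
                      cbind(c(1, 1), c(0, 0)), y[1:2, ]),
               "degenerate class")
})

test_that("n_parameters follows (K-1) + K * sum(L_j - 1)", {
  cb <- default_codebook()
  La <- vapply(cb$variables[cb$lcm_a_vars], function(v) length(v$levels), 1L)
  expect_identical(n_parameters(6, La), 209L)
  expect_identical(n_parameters(1, 2L), 1L)
  expect_identical(n_parameters(2, c(3L, 3L)), 9L)
})

test_that("fit_lca: K = 1 closed form, determinism, EM monotonicity", {
  set.seed(9)
  y <- cbind(sample(1:2, 30, TRUE), sample(1:3, 30, TRUE))
  f1 <- fit_lca(y, 1, seed = 1)
  expect_equal(f1$model$pi, 1)
  expect_equal(f1$model$p[[1]][, 1], unname(table(y[, 1]) / 30),
               ignore_attr = TRUE, tolerance = 1e-9)
  ll_direct <- sum(log(f1$model$p[[1]][y[, 1], 1])) +
    sum(log(f1$model$p[[2]][y[, 2], 1]))
  expect_equal(f1$log_likelihood, ll_direct, tolerance = 1e-10)
  expect_equal(f1$bic, -2 * ll_direct + 3 * log(30), tolerance = 1e-10)

  truth <- toy_two_class()
  d <- draw_from_model(truth, 400, seed = 5)
  fa <- fit_lca(d$y, 2, n_starts = 5, seed = 11)
  fb <- fit_lca(d$y, 2, n_starts = 5, seed = 11)
  expect_identical(fa$model, fb$model)          # bit-identical refit
  expect_identical(fa$log_likelihood, fb$log_likelihood)
  expect_true(all(diff(fa$trace) > -1e-6))      # EM monotonicity
  expect_true(fa$converged)
  # classes ordered by descending prevalence
  expect_true(all(diff(fa$model$pi) <= 1e-12))
})

test_that("fit_lca recovers a well-separated two-class structure", {
  truth <- toy_two_class(J = 6, hi = 0.9)
  d <- draw_from_model(truth, 2000, seed = 42)
  f <- fit_lca(d$y, 2, n_starts = 10, seed = 3)
  expect_lt(best_perm_error(f$model, truth), 0.05)
})

test_that("likelihood is invariant under class relabelling", {
  truth <- toy_two_class(J = 3, hi = 0.8)
  d <- draw_from_model(truth, 50, seed = 8)
  m <- fit_lca(d$y, 2, n_starts = 4, seed = 2)$model
  perm <- lca_model(m$pi[c(2, 1)],
                    lapply(m$p, function(pj) pj[, c(2, 1)]),
                    m$variable_names)
  expect_equal(log_likelihood(m, d$y), log_likelihood(perm, d$y),
               tolerance = 1e-12)
})

test_that("chi-square GOF: zero for a saturated fit, matches hand sums", {
  # single binary variable, K = 1 with p equal to empirical frequencies:
  # expected counts equal observed counts exactly
  y <- matrix(c(1L, 1L, 1L, 2L), 4, 1)
  m <- lca_model(1, list(matrix(c(0.75, 0.25), 2, 1)))
  expect_equal(chi_square_gof(m, y), 0, tolerance = 1e-12)

  # two binary variables, independence model, all four patterns observed
  y2 <- cbind(c(1L, 1L, 2L, 2L, 1L), c(1L, 2L, 1L, 2L, 1L))
  m2 <- lca_model(1, list(matrix(c(0.6, 0.4), 2, 1),
                          matrix(c(0.5, 0.5), 2, 1)))
  pr <- c(0.3, 0.3, 0.2, 0.2)          # probs of patterns 11,12,21,22
  obs <- c(2, 1, 1, 1)
  expect_equal(chi_square_gof(m2, y2), sum((obs - 5 * pr)^2 / (5 * pr)),
               tolerance = 1e-10)
  f <- fit_lca(y2, 1, seed = 1)
  expect_gte(chi_square_gof(f, y2), 0)
})

test_that("the BIC-then-chi-square local-minimum scan behaves as defined", {
  flm <- hfsubtype:::first_local_min
  expect_identical(flm(c(5, 3, 1, 2, 4)), 3L)     # interior trough
  expect_identical(flm(c(1, 2, 3)), 1L)           # one-sided left endpoint
  expect_identical(flm(c(3, 2, 1)), 3L)           # one-sided right endpoint
  expect_identical(flm(c(5, 2, 2, 1, 3)), 4L)     # plateau is not a minimum
})

test_that("select_num_classes finds a clearly separated 3-class structure", {
  p <- replicate(8, cbind(c(0.95, 0.05), c(0.5, 0.5), c(0.05, 0.95)),
                 simplify = FALSE)
  truth <- lca_model(c(1, 1, 1) / 3, p)
  d <- draw_from_model(truth, 900, seed = 31)
  sel <- select_num_classes(d$y, 2:5, n_starts = 6, seed = 7)
  expect_equal(sel$k_bic, 3L)
  # the chi-square refinement never selects below the BIC stage
  expect_gte(sel$selected_k, sel$k_bic)
  expect_false(sel$fallback_bic)
  expect_named(sel$diagnostics,
               c("K", "log_likelihood", "n_parameters", "bic", "chi_square",
                 "converged"))
})

test_that("assign_subtype is Bayesian, deterministic on ties, strict on NA", {
  # all classes identical: posterior equals the prevalences
  pj <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  m <- lca_model(c(0.7, 0.3), list(pj, pj), c("v1", "v2"))
  a <- assign_subtype(m, cbind(c(1L, 2L), c(2L, 1L)))
  expect_equal(a$posterior, matrix(c(0.7, 0.7, 0.3, 0.3), 2, 2))
  expect_equal(a$label, c(1L, 1L))   # argmax tie-free here; prevalence wins

  truth <- toy_two_class(J = 6, hi = 0.95)
  modal1 <- matrix(1L, 1, 6)          # class 1's modal profile
  a2 <- assign_subtype(truth, modal1)
  expect_equal(a2$label, 1L)
  expect_gt(a2$posterior[1, 1], 0.9)
  expect_equal(rowSums(a2$posterior), 1)

  y_na <- cbind(c(1L, NA), c(2L, 1L), c(1L, 1L), c(1L, 1L), c(1L, 1L),
                c(1L, 1L))
  expect_error(assign_subtype(truth, y_na), "missing variable 'v1'")
})

test_that("model JSON serialisation round-trips bit-exactly", {
  f <- fit_lca(draw_from_model(toy_two_class(), 120, seed = 2)$y, 2,
               n_starts = 3, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_lca_model(f, path)
  m2 <- read_lca_model(path)
  expect_identical(m2$pi, f$model$pi)
  for (j in seq_along(f$model$p))
    expect_identical(unname(m2$p[[j]]), unname(f$model$p[[j]]))
  expect_equal(attr(m2, "meta")$bic, f$bic)
})
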