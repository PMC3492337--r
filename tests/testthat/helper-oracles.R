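# Independent oracles and tiny fixtures used across the suite.  Every
# oracle is a direct enumeration / closed form, deliberately unrelated to
# the implementation paths it checks.

## brute-force latent class log-likelihood: sum_i log sum_k pi_k prod_j p
oracle_loglik <- function(pi, p, y) {
  n <- nrow(y)
  ll <- 0
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(pi)) {
      term <- pi[k]
      for (j in seq_len(ncol(y))) term <- term * p[[j]][y[i, j], k]
      s <- s + term
    }
    ll <- ll + log(s)
  }
  ll
}

## brute-force posterior by Bayes' rule
oracle_posterior <- function(pi, p, y) {
  n <- nrow(y)
  post <- matrix(0, n, length(pi))
  for (i in seq_len(n)) {
    for (k in seq_along(pi)) {
      term <- pi[k]
      for (j in seq_len(ncol(y))) term <- term * p[[j]][y[i, j], k]
      post[i, k] <- term
    }
    post[i, ] <- post[i, ] / sum(post[i, ])
  }
  post
}

## Cox partial log-likelihood by risk-set enumeration (no tied event
## times, so Breslow/Efron coincide)
oracle_cox_loglik <- function(beta, time, event, x) {
  eta <- as.matrix(x) %*% beta
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + eta[i] - log(sum(exp(eta[risk])))
  }
  as.numeric(ll)
}

## Harrell concordance by explicit pair enumeration
oracle_harrell_c <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

## a well-separated two-class binary-indicator model
toy_two_class <- function(J = 6, hi = 0.9) {
  p <- replicate(J, cbind(c(hi, 1 - hi), c(1 - hi, hi)), simplify = FALSE)
  lca_model(c(0.5, 0.5), p, paste0("v", seq_len(J)))
}

## draw a response matrix from an lca_model
draw_from_model <- function(model, n, seed) {
  set.seed(seed)
  cls <- sample.int(model$K, n, replace = TRUE, prob = model$pi)
  y <- sapply(seq_along(model$p), function(j)
    vapply(cls, function(k)
      sample.int(nrow(model$p[[j]]), 1L, prob = model$p[[j]][, k]), 1L))
  list(y = y, class = cls)
}

## best-permutation maximum absolute error between two parameter sets
best_perm_error <- function(fit_model, true_model) {
  K <- true_model$K
  perms <- asplit(as.matrix(expand.grid(rep(list(seq_len(K)), K))), 1L)
  perms <- Filter(function(pr) length(unique(pr)) == K, perms)
  best <- Inf
  for (pr in perms) {
    e <- max(abs(fit_model$pi[pr] - true_model$pi))
    for (j in seq_along(true_model$p))
      e <- max(e, max(abs(fit_model$p[[j]][, pr] - true_model$p[[j]])))
    best <- min(best, e)
  }
  best
}
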