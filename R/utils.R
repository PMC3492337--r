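# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

## round-half-up; base round() uses round-half-even which is the wrong
## convention for reconstructing counts from printed percentages
round_half_up <- function(x) floor(x + 0.5)

## numerically stable log(sum(exp(x))) by row for a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

## Dirichlet(alpha = 1) rows used for random EM initialisation
rdirichlet1 <- function(n, k) {
  g <- matrix(stats::rexp(n * k), n, k)
  g / rowSums(g)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

is_prob_vector <- function(x, tol = 1e-8) {
  is.numeric(x) && all(x >= -tol) && abs(sum(x) - 1) < tol
}

## renormalise a vector of (possibly rounded) percentages to a probability
## vector; zero entries stay exactly zero
renorm_pct <- function(x) {
  s <- sum(x)
  if (s <= 0) stopf("cannot renormalise an all-zero frequency vector")
  x / s
}
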