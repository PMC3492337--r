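test_that("harrell_c: edge cases and pair-enumeration oracle", {
  tm <- c(3, 1, 4, 2, 5); ev <- rep(1L, 5)
  expect_equal(harrell_c(tm, ev, rep(0.3, 5)), 0.5)     # all risk ties
  expect_equal(harrell_c(tm, ev, -tm), 1)               # perfect ranking
  expect_equal(harrell_c(tm, ev, tm), 0)

  tm2 <- c(2, 4, 3, 7, 5); ev2 <- c(1, 0, 1, 0, 1)
  rk <- c(0.9, 0.2, 0.6, 0.6, 0.1)
  expect_equal(harrell_c(tm2, ev2, rk), oracle_harrell_c(tm2, ev2, rk),
               tolerance = 1e-12)
  expect_error(harrell_c(c(1, 2), c(0, 0), c(0.1, 0.2)), "no usable pairs")
  expect_error(harrell_c(1:3, c(1, 1, 1), c(1, Inf, 0)), "finite")
})

test_that("harrell_c without censoring agrees with the rank-pair AUC", {
  set.seed(3)
  tm <- sample(100, 12)                 # distinct times, all events
  rk <- rnorm(12)
  # concordance of (risk, -time) over all pairs, computed via Kendall-type
  # enumeration on the binary 'earlier' relation
  expect_equal(harrell_c(tm, rep(1L, 12), rk),
               oracle_harrell_c(tm, rep(1L, 12), rk))
})

test_that("binary_c is the Mann-Whitney statistic", {
  y <- c(0, 0, 1, 1)
  expect_equal(binary_c(y, rep(0.2, 4)), 0.5)
  expect_equal(binary_c(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  # 6-point worked set: events at ranks 6, 4.5 (tie), non-events 1,2,3,4.5
  p <- c(0.1, 0.2, 0.3, 0.5, 0.5, 0.9)
  yy <- c(0, 0, 0, 0, 1, 1)
  # pairs: (p5 vs p1..p4): 1+1+1+0.5 ; (p6 vs p1..p4): 4 -> 7.5/8
  expect_equal(binary_c(yy, p), 7.5 / 8)
  expect_error(binary_c(rep(1, 4), runif(4)), "both outcome classes")
})

test_that("compare_c: identity, type-I error, and power", {
  set.seed(10)
  y <- rbinom(80, 1, 0.4); p1 <- runif(80)
  expect_equal(compare_c(p1, p1, y)$p, 1)

  rej <- vapply(1:60, function(s) {
    set.seed(200 + s)
    x1 <- rnorm(150); x2 <- rnorm(150)
    yy <- rbinom(150, 1, plogis(0.7 * x1 + 0.7 * x2))
    compare_c(plogis(x1), plogis(x2), yy)$p < 0.05
  }, TRUE)
  expect_lt(mean(rej), 0.15)   # near the nominal 5% level

  set.seed(4)
  x <- rnorm(800); yy <- rbinom(800, 1, plogis(1.5 * x))
  informative <- plogis(1.5 * x)
  noise <- plogis(0.1 * x + rnorm(800, sd = 2))
  expect_lt(compare_c(informative, noise, yy)$p, 0.05)
})

test_that("NRI components, transition matrices, and antisymmetry", {
  y <- rep(c(1, 0), c(10, 10))
  p <- rep(0.1, 20)
  r0 <- nri(p, p, y, thresholds = c(0.05, 0.15))
  expect_equal(r0$categorical$overall, 0)
  expect_equal(r0$continuous$overall, 0)

  # one event moves up one category, nothing else changes
  p_new <- p; p_new[1] <- 0.2
  r1 <- nri(p, p_new, y, thresholds = c(0.05, 0.15))
  expect_equal(r1$categorical$event, 0.1)
  expect_equal(r1$categorical$nonevent, 0)
  expect_equal(r1$categorical$overall, 0.1)
  expect_equal(sum(r1$categorical$table_events), 10)
  expect_equal(unname(r1$categorical$table_events[2, 3]), 1)

  # 20-subject hand-tabulated case
  set.seed(6)
  old <- runif(20); new <- runif(20); yy <- rbinom(20, 1, 0.5)
  th <- c(0.3, 0.6)
  r <- nri(old, new, yy, thresholds = th)
  cat_of <- function(x) findInterval(x, th) + 1
  up <- cat_of(new) > cat_of(old); dn <- cat_of(new) < cat_of(old)
  expect_equal(r$categorical$event,
               mean(up[yy == 1]) - mean(dn[yy == 1]))
  expect_equal(r$categorical$nonevent,
               mean(dn[yy == 0]) - mean(up[yy == 0]))
  # swapping old/new flips the overall component
  rs <- nri(new, old, yy, thresholds = th)
  expect_equal(rs$categorical$overall, -r$categorical$overall)
  expect_equal(rs$continuous$overall, -r$continuous$overall)

  expect_error(nri(old, new, yy, thresholds = c(0.6, 0.3)),
               "strictly increasing")
})

test_that("loocv_c is deterministic and below the apparent c on average", {
  gen <- function(seed) {
    set.seed(seed)
    n <- 120
    x1 <- rnorm(n); x2 <- rnorm(n)
    data.frame(y = rbinom(n, 1, plogis(0.8 * x1 - 0.5 * x2)),
               x1 = x1, x2 = x2, junk1 = rnorm(n), junk2 = rnorm(n))
  }
  d <- gen(1)
  r1 <- loocv_c(y ~ x1 + x2 + junk1 + junk2, d, "binomial")
  r2 <- loocv_c(y ~ x1 + x2 + junk1 + junk2, d, "binomial")
  expect_identical(r1, r2)
  expect_length(r1$failed_folds, 0)

  diffs <- vapply(1:4, function(s) {
    dd <- gen(s)
    r <- loocv_c(y ~ x1 + x2 + junk1 + junk2, dd, "binomial")
    r$apparent - r$c
  }, 0)
  expect_gt(mean(diffs), 0)   # optimism: LOOCV c below apparent c

  expect_error(loocv_c(y ~ x1, d[1:10, ], "binomial"), "n >= 20")
})

test_that("loocv_c supports Cox models on out-of-fold linear predictors", {
  set.seed(9)
  n <- 80
  x <- rnorm(n)
  tm <- rexp(n, 0.2 * exp(0.7 * x)); cs <- runif(n, 1, 10)
  d <- data.frame(time = pmin(tm, cs), event = as.integer(tm <= cs), x = x)
  r <- loocv_c(survival::Surv(time, event) ~ x, d, "cox")
  expect_true(r$c > 0.5)           # informative predictor survives LOOCV
  expect_lte(r$c, r$apparent + 0.05)
})
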