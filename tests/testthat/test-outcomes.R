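test_that("lvef_response implements the >=5-point / >=35% definition", {
  expect_equal(lvef_response(30, 36), 1L)
  expect_equal(lvef_response(30, 34), 0L)   # final below 35
  expect_equal(lvef_response(31, 35), 0L)   # improvement below 5
  expect_equal(lvef_response(30, NA), NA_integer_)
  expect_equal(lvef_response(c(30, 25), c(35, 29)), c(1L, 0L))
  expect_error(lvef_response(30, 140), "\\[0, 100\\]")
})

test_that("2x2 odds ratios match the reconstructed published rows", {
  # LVEF response, largest pathogenesis subtype: 75/89 active vs 39/114
  e <- two_by_two_odds_ratio(75, 89, 39, 114)
  expect_equal(round(e$estimate, 2), 2.46)
  # LVEF response, all subjects: 188/370 vs 105/458
  expect_equal(round(two_by_two_odds_ratio(188, 370, 105, 458)$estimate, 2),
               2.22)
  sym <- two_by_two_odds_ratio(7, 7, 7, 7)
  expect_equal(sym$estimate, 1)
  expect_true(sym$lower < 1 && sym$upper > 1)
})

test_that("2x2 odds ratio corrects zero cells and rejects zero margins", {
  z <- two_by_two_odds_ratio(0, 10, 5, 5)
  expect_true("continuity_corrected" %in% z$flags)
  expect_equal(z$estimate, (0.5 * 5.5) / (10.5 * 5.5))
  expect_error(two_by_two_odds_ratio(0, 0, 5, 5), "margin")
})

test_that("fit_logistic: intercept-only, separation, 2x2 equivalence", {
  df <- data.frame(treatment = rep(c("placebo", "bucindolol"), each = 20))
  # treatment-saturated null design: fitted probabilities are the
  # arm-specific outcome prevalences
  y2 <- rep(c(1L, 0L, 0L, 0L), 10)
  fnull <- fit_logistic(y2, df)
  expect_equal(unname(fnull$fitted),
               unname(stats::ave(y2, df$treatment)), tolerance = 1e-9)

  # outcome identical to covariate: separation flag
  ysep <- as.integer(df$treatment != "placebo")
  fsep <- fit_logistic(ysep, df)
  expect_true(fsep$separation)

  # treatment-only logistic on a saturated 2x2 equals the cross-product OR
  counts <- list(a = 188L, b = 370L, c = 105L, d = 458L)
  d22 <- data.frame(
    treatment = rep(c("bucindolol", "placebo"),
                    c(counts$a + counts$b, counts$c + counts$d)))
  y22 <- c(rep(1L, counts$a), rep(0L, counts$b),
           rep(1L, counts$c), rep(0L, counts$d))
  f22 <- fit_logistic(y22, d22)
  or_glm <- exp(stats::coef(f22$fit)[["treatment"]])
  or_cp <- two_by_two_odds_ratio(counts$a, counts$b, counts$c,
                                 counts$d)$estimate
  expect_equal(or_glm, or_cp, tolerance = 1e-6)
})

test_that("fit_logistic recovers per-subtype ORs from interactions", {
  set.seed(14)
  n <- 1200
  sub <- sample(1:3, n, TRUE)
  trt <- sample(c("placebo", "bucindolol"), n, TRUE)
  lo <- -1 + 0.8 * (trt != "placebo") * (sub == 2)   # effect only in subtype 2
  y <- rbinom(n, 1, plogis(lo))
  f <- fit_logistic(y, data.frame(treatment = trt), subtype = sub)
  expect_named(f$estimates, c("1", "2", "3"))
  # stratified single-subtype fit equals the interaction contrast
  for (s in c("1", "2")) {
    idx <- sub == as.integer(s)
    fs <- stats::glm(y[idx] ~ I(trt[idx] != "placebo"), family = binomial())
    expect_equal(log(f$estimates[[s]]$estimate),
                 unname(stats::coef(fs)[2]), tolerance = 1e-6)
  }
})

test_that("fit_ph_model matches the risk-set enumeration oracle", {
  # 6 subjects, distinct times, one covariate
  tm <- c(5, 8, 2, 9, 4, 7); ev <- c(1, 0, 1, 1, 1, 0)
  x <- c(0, 1, 1, 0, 1, 0)
  df <- data.frame(treatment = ifelse(x == 1, "bucindolol", "placebo"))
  f <- fit_ph_model(tm, ev, df)
  bhat <- stats::coef(f$fit)[["treatment"]]
  expect_equal(f$fit$loglik[2], oracle_cox_loglik(bhat, tm, ev, x),
               tolerance = 1e-10)
  b_oracle <- stats::optimize(function(b)
    -oracle_cox_loglik(b, tm, ev, x), c(-5, 5))$minimum
  expect_equal(bhat, b_oracle, tolerance = 1e-4)
})

test_that("fit_ph_model: null effect and large-sample recovery", {
  # two groups with identical event patterns -> HR 1, log-rank p ~ 1
  tm <- rep(c(1, 2, 3, 4), 2); ev <- rep(c(1, 1, 0, 1), 2)
  df <- data.frame(treatment = rep(c("placebo", "bucindolol"), each = 4))
  f <- fit_ph_model(tm, ev, df, subtype = rep(c(1, 2), 4))
  expect_equal(exp(stats::coef(f$fit)[["treatment"]]), 1, tolerance = 1e-6)

  set.seed(77)
  n <- 2000
  trt <- rep(0:1, each = n / 2)
  tt <- rexp(n, rate = 0.2 * exp(log(0.5) * trt))
  cens <- runif(n, 2, 8)
  df2 <- data.frame(treatment = ifelse(trt == 1, "bucindolol", "placebo"))
  f2 <- fit_ph_model(pmin(tt, cens), as.integer(tt <= cens), df2)
  expect_lt(abs(exp(stats::coef(f2$fit)[["treatment"]]) - 0.5), 0.1)
})

test_that("proportional-hazards checking flags time-varying effects", {
  expect_equal(nrow(test_ph_assumption(
    survival::coxph(survival::Surv(c(1, 2, 3), c(1, 1, 0)) ~ 1))), 0L)

  set.seed(5)
  n <- 800
  x <- rep(0:1, each = n / 2)
  # effect reverses over time: strong PH violation
  u <- runif(n)
  tt <- ifelse(x == 1, qexp(u, 2), qexp(u, 0.5))
  tt <- ifelse(tt > 1, tt * ifelse(x == 1, 0.2, 1.5), tt)
  f <- fit_ph_model(tt, rep(1L, n),
                    data.frame(treatment = ifelse(x == 1, "bucindolol",
                                                  "placebo")))
  expect_true(test_ph_assumption(f)$flagged[1])

  # under PH the flag rate stays near the nominal level
  flags <- vapply(1:30, function(s) {
    set.seed(100 + s)
    tt <- rexp(120, 0.3 * exp(0.4 * rep(0:1, 60)))
    fph <- fit_ph_model(tt, rep(1L, 120),
                        data.frame(treatment = rep(c("placebo", "bucindolol"),
                                                   60)))
    test_ph_assumption(fph)$flagged[1]
  }, TRUE)
  expect_lt(mean(flags), 0.2)
})

test_that("time interactions give the stated HR(t) evaluator", {
  set.seed(8)
  n <- 600
  x <- rep(0:1, each = n / 2)
  # hazard ratio rising with time: early benefit that fades
  u <- runif(n)
  tt <- ifelse(x == 1, qweibull(u, shape = 2.2, scale = 2.2),
               qweibull(u, shape = 1, scale = 2))
  df <- data.frame(treatment = ifelse(x == 1, "bucindolol", "placebo"))
  tv <- add_time_interaction(tt * 365.25, rep(1L, n), df, "treatment")
  b <- stats::coef(tv$fit)[["treatment"]]
  expect_equal(tv$hr_at("treatment", 1), exp(b), tolerance = 1e-12)
  # log HR(t) is linear in log t by construction
  lh <- log(c(tv$hr_at("treatment", 1), tv$hr_at("treatment", 2),
              tv$hr_at("treatment", 4)))
  expect_equal(lh[3] - lh[2], lh[2] - lh[1], tolerance = 1e-10)
  expect_equal(tv$hr_table$hr_gm,
               tv$hr_at("treatment", tv$geometric_mean_years),
               tolerance = 1e-12)
  hrs <- unlist(tv$hr_table[c("hr_1y", "hr_2y", "hr_3y")])
  expect_true(all(diff(hrs) > 0))   # rising-HR pattern
  expect_error(add_time_interaction(tt, rep(1L, n), df, character()),
               "no covariates")
})

test_that("km_curve matches hand-computed product-limit estimates", {
  expect_true(all(km_curve(c(1, 2, 3), c(0, 0, 0))$survival == 1))
  all1 <- km_curve(rep(1, 4), rep(1, 4))
  expect_equal(all1$survival[all1$time == 1], 0)

  # 5 subjects: death 2, censor 3, death 4, death 4, censor 6
  km <- km_curve(c(2, 3, 4, 4, 6), c(1, 0, 1, 1, 0))
  # S(2) = 4/5; S(4) = 4/5 * 1/3
  expect_equal(km$survival[km$time == 2], 0.8)
  expect_equal(km$survival[km$time == 4], 0.8 * (1 / 3), tolerance = 1e-12)
})

test_that("subtype outcome tables conserve counts and handle single arms", {
  coh <- generate_cohort(default_params(), n = 400, seed = 19, which = "A")
  oc <- coh[c("treatment", "followup_days", "death", "death_1y",
              "lvef_response")]
  tab <- subtype_outcome_table(coh$class_a, oc, prefix = "A")
  all_row <- tab[tab$subtype == "All", ]
  expect_equal(all_row$n_plac, sum(tab$n_plac[tab$subtype != "All"]))
  expect_equal(all_row$n_buc, sum(tab$n_buc[tab$subtype != "All"]))
  expect_true(all(tab$cum_mort_plac >= 0 & tab$cum_mort_plac <= 100,
                  na.rm = TRUE))

  single <- oc[oc$treatment == "placebo", ]
  tabs <- subtype_outcome_table(coh$class_a[oc$treatment == "placebo"],
                                single)
  expect_true(all(is.na(tabs$hr)))
  expect_true(all(tabs$n_buc == 0))
})
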