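test_that("default generator parameters match the published profiles", {
  p <- default_params()
  expect_equal(sum(p$lcm_a$prevalence), 1)
  expect_equal(sum(p$lcm_b$prevalence), 1)
  # printed prevalences 18.6/14.4/16.6/14.5/7.8/28.3 renormalised
  expect_equal(unname(p$lcm_a$prevalence),
               c(18.6, 14.4, 16.6, 14.5, 7.8, 28.3) / 100.2,
               tolerance = 1e-12)
  # the largest pathogenesis subtype is all male
  sex <- p$lcm_a$conditionals$sex
  expect_equal(sex[1, 6], 1)
  # severe-congestion subtype: BUN > 55 in 35% (modulo renormalisation of
  # the rounded printed column)
  bun <- p$lcm_b$conditionals$bun
  expect_equal(bun[5, 5], 0.35, tolerance = 0.02)
  # every conditional column is a simplex
  for (side in c("lcm_a", "lcm_b"))
    for (m in p[[side]]$conditionals)
      expect_equal(unname(colSums(m)), rep(1, ncol(m)), tolerance = 1e-12)
  # one-year mortality never exceeds cumulative mortality
  for (tab in p$outcome_rates) {
    expect_true(all(tab$mort1y_plac <= tab$cum_mort_plac))
    expect_true(all(tab$mort1y_buc <= tab$cum_mort_buc))
  }
})

test_that("generated class frequencies converge to the prevalences", {
  p <- default_params()
  g <- generate_features(p, n = 50000, seed = 123, which = "A")
  freq <- as.numeric(table(g$class_a)) / 50000
  expect_true(max(abs(freq - p$lcm_a$prevalence)) < 0.01)
})

test_that("generation is deterministic and degenerates correctly", {
  p <- default_params()
  g1 <- generate_cohort(p, n = 200, seed = 99, which = "both")
  g2 <- generate_cohort(p, n = 200, seed = 99, which = "both")
  expect_identical(as.data.frame(g1), as.data.frame(g2))

  # degenerate conditionals make features a deterministic map of class
  pd <- p
  for (j in seq_along(pd$lcm_a$conditionals)) {
    m <- pd$lcm_a$conditionals[[j]] * 0
    m[cbind(rep_len(seq_len(nrow(m)), ncol(m)), seq_len(ncol(m)))] <- 1
    pd$lcm_a$conditionals[[j]] <- m
  }
  gd <- generate_features(pd, n = 300, seed = 7, which = "A")
  for (j in seq_len(ncol(gd$indices_a)))
    expect_true(all(gd$indices_a[, j] ==
                    rep_len(seq_len(nrow(pd$lcm_a$conditionals[[j]])),
                            pd$lcm_a$K)[gd$class_a]))
})

test_that("piecewise hazards hit the configured one-year rate", {
  p <- default_params()
  rz <- hfsubtype:::solve_piecewise_hazard(0.077, 0.175, 3)
  expect_equal(1 - exp(-rz[["r1"]]), 0.077, tolerance = 1e-12)
  expect_equal(exp(-rz[["r1"]] - 2 * rz[["r2"]]), 1 - 0.175,
               tolerance = 1e-12)

  # B1 placebo: one-year death fraction ~ 7.7% in a large draw
  oc <- simulate_outcomes(rep(1L, 100000), rep("placebo", 100000), p,
                          seed = 31, lcm = "B")
  expect_equal(mean(oc$death_1y), 0.077, tolerance = 0.005)
  # realised LVEF response obeys its own definition
  expect_identical(oc$lvef_response,
                   lvef_response(oc$lvef_baseline_pct, oc$lvef_month12_pct))

  # zero-rate cell produces no events
  pz <- p
  pz$outcome_rates$A[1, c("cum_mort_plac", "mort1y_plac")] <- 0
  ocz <- simulate_outcomes(rep(1L, 500), rep("placebo", 500), pz,
                           seed = 2, lcm = "A")
  expect_equal(sum(ocz$death), 0L)

  # inconsistent configuration is rejected
  pbad <- p
  pbad$outcome_rates$A$cum_mort_plac[1] <- 1
  pbad$outcome_rates$A$mort1y_plac[1] <- 5
  expect_error(simulate_outcomes(rep(1L, 10), rep("placebo", 10), pbad,
                                 seed = 1, lcm = "A"), "cumulative")
})

test_that("one-year deaths are always observed deaths", {
  coh <- generate_cohort(default_params(), n = 2000, seed = 17)
  expect_true(all(coh$death[coh$death_1y == 1] == 1L))
  expect_true(all(coh$followup_days > 0))
})

test_that("cohort CSV round-trips exactly and feeds the encoder", {
  coh <- generate_cohort(default_params(), n = 50, seed = 12, which = "both")
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, path)
  back <- read_cohort(path)
  df <- as.data.frame(coh); rownames(df) <- NULL
  for (nm in names(df)) expect_identical(back[[nm]], df[[nm]], label = nm)
  expect_no_error(encode_cohort(back, default_codebook(), "A"))
  expect_no_error(encode_cohort(back, default_codebook(), "B"))

  empty <- coh[0, ]
  write_cohort(empty, path)
  expect_equal(nrow(read_cohort(path)), 0L)
})
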