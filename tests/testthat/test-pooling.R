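test_that("DerSimonian-Laird tau^2 clamps at zero and matches hand computation", {
  same <- equal_se_effects(c(0.8, 0.8))
  expect_equal(dl_tau2(same), 0)

  # the four mixed-adenocarcinoma study CIs, computed by hand from Q and C
  eff <- table3_effects()[c("emile2024", "wang2023", "wang2021", "byrne2019")]
  expect_equal(dl_tau2(eff), 0.044, tolerance = 0.01)

  spread <- equal_se_effects(c(0.2, 5), se = 0.01)
  expect_gt(dl_tau2(spread), 0)
  expect_error(dl_tau2(eff[1]), "k >= 2")
})

test_that("tau^2 and pooled estimates agree with metafor", {
  skip_if_not_installed("metafor")
  eff <- table3_effects()
  y <- vapply(eff, `[[`, 0, "log_hr")
  se <- vapply(eff, `[[`, 0, "se_log_hr")
  m <- metafor::rma(yi = y, sei = se, method = "DL", test = "knha")
  expect_equal(dl_tau2(eff), unname(m$tau2), tolerance = 1e-10)
  p <- pool(eff, mode = "none")
  expect_equal(log(p$pooled_hr), unname(as.numeric(m$beta)), tolerance = 1e-10)
  expect_equal(log(p$ci_low), unname(m$ci.lb), tolerance = 1e-6)
  expect_equal(log(p$ci_high), unname(m$ci.ub), tolerance = 1e-6)
})

test_that("pooling identities: single study, equal weights, convex hull", {
  one <- make_effect(0.7, 0.1)
  p1 <- pool(list(one), mode = "none")
  expect_equal(p1$pooled_hr, 0.7)
  expect_equal(p1$k, 1)

  eff <- equal_se_effects(c(0.5, 0.7, 0.9))
  p <- pool(eff, mode = "none")
  expect_equal(log(p$pooled_hr), mean(log(c(0.5, 0.7, 0.9))), tolerance = 1e-12)

  a <- table1_assessment()
  t3 <- table3_effects()
  logs <- vapply(t3, `[[`, 0, "log_hr")
  for (mode in c("none", "inverse_overlap")) {
    pm <- pool(t3, overlap_weights = a$weights, mode = mode)
    expect_gte(log(pm$pooled_hr), min(logs) - 1e-12)
    expect_lte(log(pm$pooled_hr), max(logs) + 1e-12)
    expect_true(pm$tau2 >= 0)
    expect_lte(pm$ci_low, pm$pooled_hr)
    expect_gte(pm$ci_high, pm$pooled_hr)
  }
})

test_that("exclusion mode drops high-overlap studies and errors when none remain", {
  eff <- equal_se_effects(c(0.5, 0.9))
  cats <- c(s1 = "high", s2 = "low")
  p <- pool(eff, mode = "exclude_high", categories = cats)
  expect_equal(p$pooled_hr, 0.9)
  expect_equal(p$k, 1)
  expect_error(pool(eff, mode = "exclude_high",
                    categories = c(s1 = "high", s2 = "high")),
               "all studies excluded")
  expect_error(pool(eff, mode = "exclude_high"), "categories")
  expect_error(pool(eff, mode = "inverse_overlap"), "overlap weights")
})

test_that("Hartung-Knapp interval approaches the normal interval for large homogeneous k", {
  set.seed(31)
  k <- 60
  eff <- lapply(seq_len(k), function(i)
    make_effect(exp(rnorm(1, log(0.8), 0.02)), 0.1, id = paste0("s", i)))
  p <- pool(eff, mode = "none")
  # normal-theory fixed-form interval with the same weights
  y <- vapply(eff, `[[`, 0, "log_hr")
  se <- vapply(eff, `[[`, 0, "se_log_hr")
  w <- 1 / (se^2 + p$tau2)
  mu <- sum(w * y) / sum(w)
  se_norm <- sqrt(1 / sum(w))
  expect_equal(log(p$ci_high) - log(p$ci_low),
               2 * qnorm(0.975) * se_norm, tolerance = 0.15)
  expect_equal(log(p$pooled_hr), mu, tolerance = 1e-12)
})

test_that("bootstrap percentile intervals are reproducible and bracket the estimate", {
  eff <- table3_effects()
  p1 <- pool(eff, mode = "none", interval = "bootstrap_percentile",
             boot_iter = 500, seed = 7)
  p2 <- pool(eff, mode = "none", interval = "bootstrap_percentile",
             boot_iter = 500, seed = 7)
  expect_identical(p1$ci_low, p2$ci_low)
  expect_lt(p1$ci_low, p1$pooled_hr)
  expect_gt(p1$ci_high, p1$pooled_hr)
  expect_error(pool(eff, mode = "none", interval = "bootstrap_percentile",
                    boot_iter = 10), "100")
})

test_that("sensitivity analysis is zero under identical strategies and hand-checkable at k=2", {
  eff <- equal_se_effects(c(0.6, 0.9))
  w <- c(s1 = 1, s2 = 1)
  cats <- c(s1 = "none", s2 = "none")
  s <- sensitivity_max_rel_diff(eff, w, cats)
  expect_equal(s$max_rel_diff_pct, 0, tolerance = 1e-9)

  cats2 <- c(s1 = "high", s2 = "none")
  s2 <- sensitivity_max_rel_diff(eff, w, cats2)
  # exclusion keeps only s2, so the largest gap is |0.9 - pooled|/pooled
  pooled <- exp(mean(log(c(0.6, 0.9))))
  expect_equal(s2$max_rel_diff_pct, abs(0.9 - pooled) / pooled * 100,
               tolerance = 1e-6)
})

test_that("pooled interval covers a homogeneous truth at the nominal rate", {
  set.seed(77)
  true_log <- log(0.7)
  hits <- 0
  reps <- 200
  for (r in seq_len(reps)) {
    eff <- lapply(1:7, function(i) {
      se <- runif(1, 0.05, 0.25)
      make_effect(exp(rnorm(1, true_log, se)), se, id = paste0("s", i))
    })
    p <- pool(eff, mode = "none")
    hits <- hits + (log(p$ci_low) <= true_log && true_log <= log(p$ci_high))
  }
  expect_gte(hits / reps, 0.90)
})

test_that("fold ratios, odds ratios and NNT reproduce the printed clinical statistics", {
  expect_equal(risk_ratio(rate_pair("x", 0.022, 0.009)), 2.4)
  expect_equal(risk_ratio(rate_pair("x", 0.069, 0.017)), 4.1)
  expect_equal(risk_ratio(rate_pair("x", 0.3, 0.3)), 1.0)
  expect_equal(odds_ratio(rate_pair("x", 0.3, 0.3)), 1.0)
  expect_equal(odds_ratio(rate_pair("x", 0.037, 0.011)), 3.45, tolerance = 0.01)
  expect_equal(odds_ratio(rate_pair("x", 0.5, 0.25)), 3.0)
  expect_equal(nnt(rate_pair("x", 0.037, 0.011)), 38L)
  expect_equal(nnt(rate_pair("x", 0.028, 0.018)), 100L)
  expect_equal(nnt(rate_pair("x", 0.874, 0.392)), 2L)
  expect_error(nnt(rate_pair("x", 0.3, 0.3)), "equal rates")
  st <- effect_stats(rate_pair("margins", 0.037, 0.011), hr = 0.30)
  expect_equal(st$nnt, 38L)
  expect_equal(st$e_value, 6.1)
})

test_that("E-values: worked values, inversion symmetry and monotonicity", {
  expect_equal(e_value(1), 1)
  expect_equal(e_value(0.13), 14.9)
  expect_equal(e_value(0.30), 6.1)
  expect_equal(e_value(2, digits = NA), 2 + sqrt(2), tolerance = 1e-12)
  for (hr in c(0.2, 0.5, 0.9, 1.3, 4)) {
    expect_equal(e_value(hr, digits = NA), e_value(1 / hr, digits = NA),
                 tolerance = 1e-12)
  }
  hrs <- c(1.1, 1.5, 2, 4, 10)
  expect_true(all(diff(vapply(hrs, e_value, 0, digits = NA)) > 0))
  ev_ci <- e_value(0.13, ci_bound = 0.17)
  expect_gt(ev_ci[["ci"]], 1)
  expect_equal(unname(e_value(0.5, ci_bound = 1.1)[["ci"]]), 1)
  expect_error(e_value(-1), "positive")
})
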