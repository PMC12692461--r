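test_that("exponential fit recovers the closed-form events/exposure rate", {
  # 3 events, 30 months of total follow-up -> rate 0.1 per month
  fit <- fit_parametric(c(5, 10, 15), c(1, 1, 1), family = "exponential")
  expect_equal(unname(fit$params[["rate"]]), 0.1, tolerance = 1e-4)
  expect_error(fit_parametric(c(5, 10), c(0, 0), family = "weibull"),
               "zero events")
})

test_that("Weibull parameter recovery within tolerance at n = 2000", {
  set.seed(11)
  n <- 2000
  t_ev <- rweibull(n, shape = 1.5, scale = 60)
  t_cn <- runif(n, 0, 160)                    # roughly 20% censoring
  time <- pmin(t_ev, t_cn); event <- as.integer(t_ev <= t_cn)
  fit <- fit_parametric(time, event, family = "weibull")
  expect_lt(abs(fit$params[["shape"]] - 1.5), 0.1)
  expect_lt(abs(fit$params[["scale"]] - 60) / 60, 0.1)
  expect_true(fit$converged)
})

test_that("generalized gamma nests Weibull and log-normal in log-likelihood", {
  set.seed(12)
  t_ev <- rweibull(400, 1.3, 50)
  ev <- rep(1, 400)
  ll <- vapply(c("weibull", "lognormal", "gengamma"), function(f)
    fit_parametric(t_ev, ev, family = f)$loglik, 0)
  expect_gte(ll[["gengamma"]], ll[["weibull"]] - 1e-4)
  expect_gte(ll[["gengamma"]], ll[["lognormal"]] - 1e-4)
})

test_that("survival functions honour family identities", {
  fit_exp <- list(family = "exponential", params = c(rate = 0.1))
  expect_equal(survival_at(fit_exp, 0), 1)
  expect_equal(survival_at(fit_exp, 10), exp(-1))
  fit_wb <- list(family = "weibull", params = c(shape = 1, scale = 10))
  expect_equal(survival_at(fit_wb, c(0, 5, 10, 60)),
               survival_at(fit_exp, c(0, 5, 10, 60)))
  expect_equal(five_year_os(fit_exp), exp(-6) * 100)
  expect_error(survival_at(fit_exp, -1), "negative")
})

test_that("two-stage pooling passes through identical fits and flags singletons", {
  set.seed(13)
  t_ev <- rweibull(500, 1.4, 70)
  fit <- fit_parametric(t_ev, rep(1, 500), family = "weibull")
  pooled <- two_stage_pool(list(a = fit, b = fit, c = fit))
  expect_equal(pooled$params, fit$params, tolerance = 1e-8)
  expect_equal(unname(pooled$tau2), rep(0, 2), tolerance = 1e-10)
  single <- two_stage_pool(list(a = fit))
  expect_true(single$passthrough)
  fit_ln <- fit_parametric(t_ev, rep(1, 500), family = "lognormal")
  expect_error(two_stage_pool(list(fit, fit_ln)), "different families")
})

test_that("two-stage pooling recovers a between-study scale spread", {
  set.seed(14)
  reps <- 20
  sds <- vapply(seq_len(reps), function(r) {
    fits <- lapply(1:8, function(s) {
      scl <- exp(rnorm(1, log(60), 0.2))
      tm <- rweibull(400, 1.4, scl)
      fit_parametric(tm, rep(1, 400), family = "weibull")
    })
    names(fits) <- paste0("s", 1:8)
    sqrt(two_stage_pool(fits)$tau2[["scale"]])
  }, 0)
  expect_lt(abs(mean(sds) - 0.2), 0.1)
})

test_that("C-index matches enumeration, brute force and the survival package", {
  expect_equal(c_index(c(1, 2, 3), c(5, 4, 1), c(1, 1, 1)), 1)
  # anti-ranked scores, all events
  expect_equal(c_index(10:1, 1:10, rep(1, 10)), 1)
  # brute-force oracle at n <= 50
  brute <- function(sc, tm, ev) {
    num <- den <- 0
    for (i in seq_along(sc)) for (j in seq_along(sc)) {
      if (i >= j) next
      for (pair in list(c(i, j), c(j, i))) {
        a <- pair[1]; b <- pair[2]
        usable <- (tm[a] < tm[b] && ev[a] == 1) ||
                  (tm[a] == tm[b] && ev[a] == 1 && ev[b] == 0)
        if (usable) {
          den <- den + 1
          if (sc[a] > sc[b]) num <- num + 1
          else if (sc[a] == sc[b]) num <- num + 0.5
        }
      }
    }
    num / den
  }
  set.seed(15)
  for (rep in 1:8) {
    n <- sample(10:50, 1)
    sc <- sample(1:6, n, replace = TRUE)          # ties in scores
    tm <- round(rexp(n, 0.1), 1)
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) next
    expect_equal(c_index(sc, tm, ev), brute(sc, tm, ev))
  }
  # agreement with survival::concordance on tie-free data
  set.seed(16)
  sc <- runif(80); tm <- rexp(80); ev <- rbinom(80, 1, 0.6)
  expect_equal(c_index(sc, tm, ev),
               1 - survival::concordance(survival::Surv(tm, ev) ~ sc)$concordance,
               tolerance = 1e-12)
  # random scores are uninformative
  set.seed(17)
  sc <- runif(2000); tm <- rexp(2000); ev <- rbinom(2000, 1, 0.7)
  expect_lt(abs(c_index(sc, tm, ev) - 0.5), 0.03)
  expect_error(c_index(1, 5, 0), "no comparable pairs")
})

test_that("Hosmer-Lemeshow is zero for perfectly calibrated groups and large for gross miscalibration", {
  # ten groups whose observed event counts equal the expected counts exactly
  probs <- seq(0.05, 0.5, by = 0.05)
  pred <- rep(probs, each = 20)
  outcome <- unlist(lapply(probs, function(p)
    c(rep(1, round(20 * p)), rep(0, 20 - round(20 * p)))))
  hl <- hosmer_lemeshow(pred, outcome)
  expect_equal(hl$statistic, 0, tolerance = 1e-9)
  expect_equal(hl$df, 8)

  set.seed(18)
  pred2 <- runif(500, 0.4, 0.6)
  out2 <- rbinom(500, 1, 0.05)                   # far off the predictions
  hl2 <- hosmer_lemeshow(pred2, out2)
  expect_gt(hl2$statistic, 50)
  expect_lt(hl2$p_value, 1e-6)

  set.seed(19)
  pred3 <- runif(5000)
  out3 <- rbinom(5000, 1, pred3)                 # well calibrated
  hl3 <- hosmer_lemeshow(pred3, out3)
  expect_gt(hl3$p_value, 0.001)
  expect_lt(hl3$statistic / hl3$df, 4)
  expect_error(hosmer_lemeshow(runif(5), rbinom(5, 1, 0.5), bins = 10),
               "at least as many")
})

test_that("reclassification metrics follow their definitions", {
  idt <- reclassification(c(1, 2, 2, 3), c(1, 2, 2, 3), c(1, 0, 1, 0))
  expect_equal(idt$nri, 0)
  up <- reclassification(old = c(1, 1, 2, 2), new = c(2, 2, 2, 2),
                         outcome = c(1, 1, 0, 0))
  expect_equal(up$nri, 1)
  # 2 events up, 1 non-event up, 1 non-event down
  ex <- reclassification(old = c(1, 1, 2, 2), new = c(2, 2, 3, 1),
                         outcome = c(1, 1, 0, 0))
  expect_equal(ex$nri, 1 + 0)
  expect_gte(ex$nri, -2); expect_lte(ex$nri, 2)
  same_p <- runif(4)
  expect_equal(reclassification(c(1, 1, 2, 2), c(1, 1, 2, 2), c(1, 1, 0, 0),
                                p_old = same_p, p_new = same_p)$idi, 0)
  expect_error(reclassification(1:2, 1:2, c(1, 1)), "non-events")
})

test_that("net benefit obeys its closed-form identities", {
  out <- c(rep(1, 30), rep(0, 70))
  # classify-none: no prediction reaches the threshold
  expect_equal(net_benefit(rep(0.01, 100), out, 0.5), 0)
  # perfect predictor attains prevalence at any threshold
  perfect <- ifelse(out == 1, 0.99, 0.01)
  for (pt in c(0.15, 0.3, 0.6))
    expect_equal(net_benefit(perfect, out, pt), 0.3)
  # all-positive classifier at threshold = prevalence is worthless
  expect_equal(net_benefit(rep(0.99, 100), out, 0.3), 0, tolerance = 1e-12)
  expect_error(net_benefit(perfect, out, 1), "strictly inside")
})

test_that("risk tiers are total, deterministic and match the descriptor rules", {
  expect_equal(assign_risk_tier(list(histology = "NET", stage = "localized",
                                     age = 50))$tier, "very_low")
  expect_equal(assign_risk_tier(list(histology = "SRCC", stage = "IV",
                                     margins = "positive"))$tier, "very_high")
  expect_equal(assign_risk_tier(list(histology = "GCA", stage = "I",
                                     margins = "negative"))$tier, "low")
  expect_equal(assign_risk_tier(list(histology = "MAC", stage = "II",
                                     age = 70))$tier, "intermediate")
  expect_equal(assign_risk_tier(list(histology = "NMAC", stage = "IV"))$tier,
               "high")
  miss <- assign_risk_tier(list(histology = "MAC"))
  expect_true(miss$insufficient_data)
  expect_true(is.na(miss$tier))

  grid <- expand.grid(histology = c("MAC", "NMAC", "GCA", "SRCC", "NET",
                                    "MiNEN"),
                      stage = c("I", "II", "III", "IV", "localized",
                                "regional", "distant"),
                      age = c(40, 70),
                      margins = c("positive", "negative"),
                      hipec = c(TRUE, FALSE),
                      stringsAsFactors = FALSE)
  tiers <- assign_risk_tiers(grid)
  expect_true(all(tiers$tier %in% c("very_low", "low", "intermediate",
                                    "high", "very_high")))
  tiers2 <- assign_risk_tiers(grid)
  expect_identical(tiers$tier, tiers2$tier)
})

test_that("brier score and calibration slope behave at the reference points", {
  out <- c(1, 0, 1, 0)
  expect_equal(brier_score(c(1, 0, 1, 0), out), 0)
  expect_equal(brier_score(c(0, 1, 0, 1), out), 1)
  set.seed(20)
  p <- runif(3000, 0.05, 0.95)
  y <- rbinom(3000, 1, p)
  expect_equal(calibration_slope(p, y), 1, tolerance = 0.15)
})
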