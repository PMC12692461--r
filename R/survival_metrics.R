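# Parametric survival fitting, two-stage hierarchical pooling, and the
# discrimination/calibration metric suite (C-index, Hosmer-Lemeshow,
# reclassification, Brier, net benefit) plus rule-based risk-tier assignment.

FAMILY_MAP <- c(weibull = "weibull", lognormal = "lnorm",
                gengamma = "gengamma", exponential = "exp")

#' Fit a parametric survival model to right-censored IPD
#'
#' Maximum-likelihood fit of a Weibull, log-normal, generalized gamma or
#' exponential survival distribution (via \pkg{flexsurv}); the generalized
#' gamma nests both Weibull and log-normal, and a Weibull with shape 1 is
#' exponential. Parameters are reported on both the natural and the
#' unconstrained (log for positive parameters) scales, the latter with
#' standard errors from the observed information — these feed the two-stage
#' hierarchical pooling.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicators (1 event, 0 censored); at least one event.
#' @param family One of "weibull", "lognormal", "gengamma", "exponential".
#' @return An object of class `parametric_fit` with fields `family`,
#'   `params` (natural scale), `params_t`, `se_t` (unconstrained scale),
#'   `loglik`, `n`, `events`, `converged`.
#' @export
fit_parametric <- function(time, event,
                           family = c("weibull", "lognormal", "gengamma",
                                      "exponential")) {
  family <- match.arg(family)
  if (length(time) != length(event)) stop_domain("time/event length mismatch")
  if (sum(event) < 1) stop_domain("cannot fit with zero events")
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1,
                          dist = FAMILY_MAP[[family]]),
    error = function(e) stop_domain("parametric fit failed: ",
                                    conditionMessage(e)))
  res_t <- fit$res.t
  structure(list(
    family = family,
    params = setNames(fit$res[, "est"], rownames(fit$res)),
    params_t = setNames(res_t[, "est"], rownames(res_t)),
    se_t = setNames(res_t[, "se"], rownames(res_t)),
    loglik = fit$loglik,
    n = length(time),
    events = sum(event),
    converged = is.finite(fit$loglik) && all(is.finite(res_t[, "se"]))
  ), class = "parametric_fit")
}

#' @export
print.parametric_fit <- function(x, ...) {
  cat(sprintf("<parametric_fit> %s: %s; loglik %.2f (n=%d, events=%d)\n",
              x$family,
              paste(sprintf("%s=%.4g", names(x$params), x$params),
                    collapse = ", "),
              x$loglik, x$n, x$events))
  invisible(x)
}

#' Survival function of a fitted or pooled parametric model
#'
#' @param fit A `parametric_fit`, or a list with `family` and natural-scale
#'   `params` (e.g. the pooled output of [two_stage_pool()]).
#' @param t Times, `>= 0`.
#' @return `S(t)` for each time.
#' @export
survival_at <- function(fit, t) {
  if (any(t < 0)) stop_domain("negative time")
  p <- fit$params
  switch(fit$family,
    weibull = 1 - stats::pweibull(t, shape = p[["shape"]], scale = p[["scale"]]),
    lognormal = 1 - stats::plnorm(t, meanlog = p[["meanlog"]],
                                  sdlog = p[["sdlog"]]),
    gengamma = 1 - flexsurv::pgengamma(t, mu = p[["mu"]], sigma = p[["sigma"]],
                                       Q = p[["Q"]]),
    exponential = exp(-p[["rate"]] * t),
    stop_domain("unknown family: ", fit$family))
}

#' Five-year overall survival (percent) implied by a parametric fit
#' @param fit A `parametric_fit` or pooled parameter list.
#' @return `S(60 months) * 100`.
#' @export
five_year_os <- function(fit) unname(survival_at(fit, 60) * 100)

#' Pool per-study parametric fits in two stages
#'
#' Stage one fits each study separately ([fit_parametric()]); stage two
#' combines each unconstrained-scale parameter across studies by
#' overlap-aware random-effects pooling with Hartung-Knapp intervals — a
#' two-stage frequentist realisation of a hierarchical model with a random
#' study effect on every parameter.
#'
#' @param fits List of `parametric_fit`s, all of the same family.
#' @param overlap_weights Optional named inverse-overlap study weights; the
#'   list names of `fits` are the study ids.
#' @return List with `family`, `params` (pooled natural scale), `params_t`,
#'   `ci_t` (per-parameter HK intervals), `tau2` (between-study variance per
#'   parameter) and `k`; a single fit is passed through with a flag.
#' @export
two_stage_pool <- function(fits, overlap_weights = NULL) {
  fams <- unique(vapply(fits, `[[`, "", "family"))
  if (length(fams) != 1L)
    stop_domain("cannot pool fits of different families: ",
                paste(fams, collapse = ", "))
  ids <- names(fits) %||% paste0("study", seq_along(fits))
  if (length(fits) == 1L) {
    f <- fits[[1]]
    return(list(family = f$family, params = f$params, params_t = f$params_t,
                ci_t = NULL, tau2 = setNames(rep(0, length(f$params_t)),
                                             names(f$params_t)),
                k = 1L, passthrough = TRUE))
  }
  par_names <- names(fits[[1]]$params_t)
  pooled_t <- tau2 <- setNames(numeric(length(par_names)), par_names)
  ci_t <- matrix(NA_real_, length(par_names), 2,
                 dimnames = list(par_names, c("low", "high")))
  mode <- if (is.null(overlap_weights)) "none" else "inverse_overlap"
  for (pn in par_names) {
    eff <- lapply(seq_along(fits), function(i) {
      y <- fits[[i]]$params_t[[pn]]
      se <- fits[[i]]$se_t[[pn]]
      effect_from_ci(exp(y), exp(y - qnorm(0.975) * se),
                     exp(y + qnorm(0.975) * se), study_id = ids[i])
    })
    pe <- pool(eff, overlap_weights = overlap_weights, mode = mode)
    pooled_t[pn] <- log(pe$pooled_hr)
    ci_t[pn, ] <- log(c(pe$ci_low, pe$ci_high))
    tau2[pn] <- pe$tau2
  }
  # invert the transform: parameters with log-scale inference are positive
  nat <- pooled_t
  log_scale <- abs(fits[[1]]$params_t - log(pmax(fits[[1]]$params, 1e-300))) < 1e-6 &
               fits[[1]]$params > 0
  nat[log_scale] <- exp(pooled_t[log_scale])
  list(family = fams, params = nat, params_t = pooled_t, ci_t = ci_t,
       tau2 = tau2, k = length(fits), passthrough = FALSE)
}

#' Harrell's concordance index
#'
#' Fraction of usable pairs in which the patient with the higher risk score
#' has the shorter survival; tied scores get half credit. A pair is usable
#' when the shorter observed time ends in an event (or, at tied times, when
#' exactly one of the two has an event).
#'
#' @param scores Risk scores (higher = predicted shorter survival).
#' @param times Observed times.
#' @param events Event indicators.
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(scores, times, events) {
  n <- length(scores)
  if (length(times) != n || length(events) != n)
    stop_domain("scores/times/events length mismatch")
  conc <- disc <- ties <- 0
  for (i in seq_len(n - 1)) {
    j <- seq(i + 1, n)
    ti <- times[i]; tj <- times[j]
    # usable: earlier observed time has an event; tied times need exactly one event
    usable_i <- ti < tj & events[i] == 1
    usable_j <- tj < ti & events[j] == 1
    usable_tie <- ti == tj & (events[i] + events[j] == 1)
    short_i <- usable_i | (usable_tie & events[i] == 1)
    short_j <- usable_j | (usable_tie & events[j] == 1)
    ds <- scores[i] - scores[j]
    conc <- conc + sum(short_i & ds > 0) + sum(short_j & ds < 0)
    disc <- disc + sum(short_i & ds < 0) + sum(short_j & ds > 0)
    ties <- ties + sum((short_i | short_j) & ds == 0)
  }
  total <- conc + disc + ties
  if (total == 0) stop_domain("no comparable pairs")
  (conc + 0.5 * ties) / total
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Decile-of-risk binning of predicted probabilities;
#' `chi^2 = sum (O - E)^2 / (E (1 - E / n_g))` over bins, compared to a
#' chi-squared distribution with `bins - 2` degrees of freedom. Bins left
#' empty by tied predictions are merged with their neighbour (with a
#' message).
#'
#' @param pred Predicted event probabilities in `[0, 1]`.
#' @param outcome Observed binary outcomes.
#' @param bins Number of risk groups (default 10).
#' @return List with `statistic`, `df`, `p_value`, `n_bins`.
#' @export
hosmer_lemeshow <- function(pred, outcome, bins = 10) {
  n <- length(pred)
  if (length(outcome) != n) stop_domain("pred/outcome length mismatch")
  if (n < bins) stop_domain("need at least as many observations as bins")
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = bins + 1),
                        names = FALSE))
  if (length(br) - 1 < bins)
    message("merging empty risk bins: ", bins, " -> ", length(br) - 1)
  grp <- cut(pred, breaks = br, include.lowest = TRUE)
  O <- tapply(outcome, grp, sum)
  E <- tapply(pred, grp, sum)
  ng <- tapply(rep(1, n), grp, sum)
  keep <- !is.na(O)
  O <- O[keep]; E <- E[keep]; ng <- ng[keep]
  denom <- E * (1 - E / ng)
  denom[denom < 1e-12] <- 1e-12
  stat <- sum((O - E)^2 / denom)
  df <- max(length(O) - 2, 1)
  list(statistic = unname(stat), df = df,
       p_value = unname(1 - pchisq(stat, df)), n_bins = length(O))
}

#' Net reclassification and integrated discrimination improvement
#'
#' `NRI = [P(up | event) - P(down | event)] + [P(down | non-event) -
#' P(up | non-event)]` for a move from `old` to `new` risk tiers (ordered);
#' `IDI = (mean p_new - mean p_old | events) - (mean p_new - mean p_old |
#' non-events)` when predicted probabilities are supplied.
#'
#' @param old,new Risk classifications, comparable by order (ordered factors
#'   or numeric tier ranks).
#' @param outcome Binary outcomes; both classes must be present.
#' @param p_old,p_new Optional predicted probabilities for the IDI.
#' @return List with `nri` (and components) and `idi` (`NA` without
#'   probabilities).
#' @export
reclassification <- function(old, new, outcome, p_old = NULL, p_new = NULL) {
  n <- length(outcome)
  if (length(old) != n || length(new) != n)
    stop_domain("classification/outcome length mismatch")
  if (!any(outcome == 1) || !any(outcome == 0))
    stop_domain("NRI undefined without both events and non-events")
  rank_of <- function(x) if (is.factor(x)) as.integer(x) else as.numeric(x)
  up <- rank_of(new) > rank_of(old)
  down <- rank_of(new) < rank_of(old)
  ev <- outcome == 1
  nri_ev <- mean(up[ev]) - mean(down[ev])
  nri_ne <- mean(down[!ev]) - mean(up[!ev])
  idi <- NA_real_
  if (!is.null(p_old) && !is.null(p_new))
    idi <- (mean(p_new[ev]) - mean(p_old[ev])) -
           (mean(p_new[!ev]) - mean(p_old[!ev]))
  list(nri = nri_ev + nri_ne, nri_events = nri_ev, nri_nonevents = nri_ne,
       idi = idi)
}

#' Brier score
#' @param pred Predicted probabilities.
#' @param outcome Binary outcomes.
#' @return Mean squared prediction error in `[0, 1]`.
#' @export
brier_score <- function(pred, outcome) mean((pred - outcome)^2)

#' Calibration slope
#'
#' Slope of the logistic regression of outcomes on the logit of the
#' predicted probabilities (1 = perfectly calibrated spread).
#'
#' @param pred Predicted probabilities strictly inside (0, 1).
#' @param outcome Binary outcomes.
#' @return Slope estimate.
#' @export
calibration_slope <- function(pred, outcome) {
  lp <- log(pred / (1 - pred))
  unname(stats::coef(stats::glm(outcome ~ lp, family = stats::binomial()))[2])
}

#' Net benefit at a decision threshold
#'
#' `TP/n - FP/n * threshold / (1 - threshold)` for the policy "treat when the
#' predicted probability reaches the threshold"; classify-none has net
#' benefit 0 by definition, and a perfect predictor attains the event
#' prevalence at every threshold.
#'
#' @param pred Predicted probabilities.
#' @param outcome Binary outcomes.
#' @param threshold Decision threshold strictly inside (0, 1); may be a
#'   vector.
#' @return Net benefit per threshold.
#' @export
net_benefit <- function(pred, outcome, threshold) {
  if (any(threshold <= 0) || any(threshold >= 1))
    stop_domain("thresholds must lie strictly inside (0, 1)")
  n <- length(pred)
  vapply(threshold, function(pt) {
    pos <- pred >= pt
    tp <- sum(pos & outcome == 1)
    fp <- sum(pos & outcome == 0)
    tp / n - fp / n * pt / (1 - pt)
  }, 0)
}

RISK_TIERS <- c("very_low", "low", "intermediate", "high", "very_high")

stage_is_early <- function(stage) {
  tolower(stage) %in% c("i", "ii", "i-ii", "localized", "local", "early")
}
stage_is_advanced <- function(stage) {
  tolower(stage) %in% c("iv", "distant", "metastatic")
}

#' Assign a patient to a five-tier risk category
#'
#' Deterministic rule-based stratification mapping cohort-level descriptors
#' to patient-level predicates, evaluated in fixed precedence (very_high,
#' high, intermediate, low, very_low; first match wins, default
#' intermediate):
#' \itemize{
#'   \item very_high — at least three adverse factors among signet-ring
#'     histology, stage IV/distant disease, positive margins, HIPEC-level
#'     surgical complexity;
#'   \item high — any of signet-ring histology, stage IV/distant disease or
#'     positive margins;
#'   \item intermediate — mucinous or non-mucinous adenocarcinoma (the mixed
#'     mid-risk bulk of the cohort);
#'   \item low — goblet-cell histology with early-stage disease and margins
#'     not positive;
#'   \item very_low — neuroendocrine/carcinoid histology, localized disease,
#'     age under 55.
#' }
#' Records missing histology or stage get tier `NA` with an
#' insufficient-data flag rather than a guess.
#'
#' @param record List or one-row data frame with fields `histology`,
#'   `stage`, and optionally `age`, `margins` ("positive"/"negative") and
#'   `hipec` (logical).
#' @return An object of class `risk_tier`: list with `tier`, `rule` (the
#'   triggering rule) and `insufficient_data`.
#' @export
assign_risk_tier <- function(record) {
  record <- as.list(record)
  hist <- record$histology %||% NA
  stage <- record$stage %||% NA
  if (is.na(hist) || is.na(stage)) {
    return(structure(list(tier = NA_character_, rule = "missing fields",
                          insufficient_data = TRUE), class = "risk_tier"))
  }
  age <- record$age %||% NA_real_
  margins <- tolower(record$margins %||% NA_character_)
  hipec <- isTRUE(record$hipec)
  srcc <- toupper(hist) == "SRCC"
  adv <- stage_is_advanced(stage)
  pos_margin <- identical(margins, "positive")
  adverse <- sum(srcc, adv, pos_margin, hipec)
  res <- if (adverse >= 3) {
    list("very_high", "multiple adverse factors")
  } else if (srcc || adv || pos_margin) {
    list("high", "SRCC presence, advanced stage or positive margins")
  } else if (toupper(hist) %in% c("MAC", "NMAC")) {
    list("intermediate", "adenocarcinoma histology, mixed staging")
  } else if (toupper(hist) == "GCA" && stage_is_early(stage) && !pos_margin) {
    list("low", "GCA histology, early stage, margins not positive")
  } else if (toupper(hist) %in% c("NET", "CARCINOID") && stage_is_early(stage) &&
             !is.na(age) && age < 55) {
    list("very_low", "NET/carcinoid dominant, localized disease, age < 55")
  } else {
    list("intermediate", "default")
  }
  structure(list(tier = res[[1]], rule = res[[2]], insufficient_data = FALSE),
            class = "risk_tier")
}

#' Assign risk tiers to a cohort table
#'
#' @param cohort Data frame with the fields of [assign_risk_tier()].
#' @return Data frame with `tier`, `triggered_rule`, `insufficient_data`
#'   columns appended.
#' @export
assign_risk_tiers <- function(cohort) {
  res <- lapply(seq_len(nrow(cohort)), function(i)
    assign_risk_tier(cohort[i, , drop = FALSE]))
  cohort$tier <- vapply(res, `[[`, "", "tier")
  cohort$triggered_rule <- vapply(res, `[[`, "", "rule")
  cohort$insufficient_data <- vapply(res, `[[`, TRUE, "insufficient_data")
  cohort
}
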