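# Derived clinical-effect statistics from rate pairs and hazard ratios.

#' Risk (fold) ratio of a rate pair
#'
#' `p_exposed / p_reference`, the "x-fold" figure of clinical summaries.
#'
#' @param rates A [rate_pair()].
#' @param digits Decimal places for the reported value (default 1, matching
#'   the usual "2.4-fold" convention); use `NA` for the raw ratio.
#' @return Fold ratio.
#' @export
risk_ratio <- function(rates, digits = 1) {
  stopifnot(inherits(rates, "rate_pair"))
  rr <- rates$p_exposed / rates$p_reference
  if (is.na(digits)) rr else round(rr, digits)
}

#' Odds ratio of a rate pair
#'
#' `(p1/(1-p1)) / (p0/(1-p0))`. Note that for small rates the odds ratio and
#' the risk ratio are close but not identical; both are computed and should
#' be labelled explicitly.
#'
#' @param rates A [rate_pair()].
#' @return Odds ratio.
#' @export
odds_ratio <- function(rates) {
  stopifnot(inherits(rates, "rate_pair"))
  (rates$p_exposed / (1 - rates$p_exposed)) /
    (rates$p_reference / (1 - rates$p_reference))
}

#' Absolute risk reduction of a rate pair
#' @param rates A [rate_pair()].
#' @return `p_reference - p_exposed` (positive when exposure lowers the rate).
#' @export
arr <- function(rates) {
  stopifnot(inherits(rates, "rate_pair"))
  rates$p_reference - rates$p_exposed
}

#' Number needed to treat
#'
#' `round(1 / |p_exposed - p_reference|)` to the nearest integer; undefined
#' (error) for equal rates.
#'
#' @param rates A [rate_pair()].
#' @return Integer NNT.
#' @export
nnt <- function(rates) {
  stopifnot(inherits(rates, "rate_pair"))
  d <- abs(rates$p_exposed - rates$p_reference)
  if (d == 0) stop_domain("NNT undefined for equal rates")
  as.integer(round(1 / d))
}

#' E-value for unmeasured confounding
#'
#' The minimum strength of association (risk-ratio scale) an unmeasured
#' confounder would need with both treatment and outcome to fully explain an
#' observed hazard ratio. Protective ratios (`hr < 1`) are inverted first:
#' `RR* = max(hr, 1/hr)`, `E = RR* + sqrt(RR* * (RR* - 1))`; `hr = 1` gives
#' `E = 1`. When a CI bound is supplied, the E-value for the bound closer to
#' the null is returned alongside (1 if the CI crosses the null).
#'
#' @param hr Hazard ratio, `> 0`.
#' @param ci_bound Optional CI bound closer to the null.
#' @param digits Decimal places for reporting (default 1); `NA` for raw.
#' @return E-value, or a named vector `c(point, ci)` when `ci_bound` given.
#' @export
e_value <- function(hr, ci_bound = NULL, digits = 1) {
  ev1 <- function(r) {
    if (!is_scalar_number(r) || r <= 0)
      stop_domain("hazard ratio must be positive")
    rs <- max(r, 1 / r)
    e <- rs + sqrt(rs * (rs - 1))
    if (is.na(digits)) e else round(e, digits)
  }
  point <- ev1(hr)
  if (is.null(ci_bound)) return(point)
  crosses <- (hr < 1 && ci_bound >= 1) || (hr > 1 && ci_bound <= 1)
  c(point = point, ci = if (crosses) 1 else ev1(ci_bound))
}

#' All derived effect statistics for a rate pair
#'
#' @param rates A [rate_pair()].
#' @param hr Optional hazard ratio for the same comparison (adds an E-value).
#' @return An object of class `effect_stats` with `risk_ratio`, `odds_ratio`,
#'   `arr`, `nnt` and optional `e_value`.
#' @export
effect_stats <- function(rates, hr = NULL) {
  structure(list(label = rates$label,
                 risk_ratio = risk_ratio(rates),
                 odds_ratio = odds_ratio(rates),
                 arr = arr(rates),
                 nnt = nnt(rates),
                 e_value = if (!is.null(hr)) e_value(hr) else NA_real_),
            class = "effect_stats")
}

#' @export
print.effect_stats <- function(x, ...) {
  cat(sprintf("<effect_stats> %s: RR %.1f, OR %.2f, ARR %.3f, NNT %d%s\n",
              x$label, x$risk_ratio, x$odds_ratio, x$arr, x$nnt,
              if (is.na(x$e_value)) "" else sprintf(", E-value %.1f", x$e_value)))
  invisible(x)
}
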