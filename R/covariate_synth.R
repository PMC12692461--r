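# Gaussian-copula synthesis of patient-level covariates matching published
# marginal summaries. A latent multivariate normal vector with unit variances
# and a specified correlation matrix is transformed coordinate-wise through
# each variable's quantile function: categorical variables by
# probability-slice inversion of the latent normal CDF (ordered categories
# use the same thresholds, which makes them ordinal cut points on the latent
# scale), continuous variables by a truncated-normal quantile map. Several
# candidate dependence models can be averaged: each patient block is drawn
# from a candidate selected with probability proportional to the candidate
# weights (pseudo-likelihood BIC weights by default).

#' Specify a synthetic cohort
#'
#' @param n Cohort size.
#' @param marginals Named list, one entry per variable: a named numeric
#'   vector of category probabilities summing to 1 (categorical), or a list
#'   with `mean`, `sd` and optional `min`, `max` (truncated-normal
#'   continuous).
#' @param dependence Correlation matrix for the latent Gaussian copula
#'   (dimnames matching the variables); `NULL` for independence.
#' @param candidates Optional named list of candidate dependence models, each
#'   a correlation matrix or `NULL` (independence), with an optional
#'   `weights` attribute. Defaults to the single `dependence` model.
#' @param seed Mandatory integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n, marginals, dependence = NULL, candidates = NULL,
                        seed) {
  if (!is_scalar_number(n) || n < 1) stop_domain("n must be a positive integer")
  if (missing(seed) || !is_scalar_number(seed))
    stop_domain("an integer seed is mandatory")
  if (!length(marginals) || is.null(names(marginals)))
    stop_domain("marginals must be a named list")
  for (v in names(marginals)) {
    m <- marginals[[v]]
    if (is.numeric(m)) {
      if (is.null(names(m)) || any(m < 0))
        stop_domain("categorical marginal '", v,
                    "' needs named non-negative probabilities")
      if (abs(sum(m) - 1) > 1e-9)
        stop_domain("categorical marginal '", v, "' sums to ",
                    signif(sum(m), 8), ", not 1")
    } else if (is.list(m)) {
      if (!is_scalar_number(m$mean %||% NA) || !is_scalar_number(m$sd %||% NA) ||
          m$sd <= 0)
        stop_domain("continuous marginal '", v, "' needs mean and sd > 0")
    } else stop_domain("marginal '", v, "' must be a probability vector or list")
  }
  vars <- names(marginals)
  check_corr <- function(R, label) {
    if (is.null(R)) return(NULL)
    R <- as.matrix(R)
    if (is.null(dimnames(R))) dimnames(R) <- list(vars, vars)
    if (!all(vars %in% rownames(R)))
      stop_domain("dependence model '", label, "' misses variables")
    R <- R[vars, vars]
    if (max(abs(R - t(R))) > 1e-9 || max(abs(diag(R) - 1)) > 1e-9)
      stop_domain("dependence model '", label,
                  "' must be symmetric with unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop_domain("dependence model '", label,
                  "' is not positive semi-definite")
    R
  }
  dependence <- check_corr(dependence, "dependence")
  if (is.null(candidates)) {
    candidates <- list(primary = dependence)
  } else {
    w <- attr(candidates, "weights")
    candidates <- lapply(seq_along(candidates), function(i)
      check_corr(candidates[[i]], names(candidates)[i] %||% i))
    names(candidates) <- names(candidates) %||% paste0("cand", seq_along(candidates))
    attr(candidates, "weights") <- w
  }
  structure(list(n = as.integer(n), marginals = marginals,
                 dependence = dependence, candidates = candidates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

latent_draw <- function(n, R, p) {
  Z <- matrix(rnorm(n * p), n, p)
  if (!is.null(R)) {
    ev <- eigen(R, symmetric = TRUE)
    L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), p) %*% t(ev$vectors)
    Z <- Z %*% L
  }
  Z
}

transform_margin <- function(z, m, vname) {
  if (is.numeric(m)) {
    # probability-slice inversion: cut points of the latent normal CDF at the
    # cumulative category probabilities (ordinal thresholds for ordered sets)
    u <- pnorm(z)
    br <- c(0, cumsum(m))
    br[length(br)] <- 1
    idx <- findInterval(u, br, rightmost.closed = TRUE, left.open = TRUE)
    idx[idx < 1] <- 1L
    factor(names(m)[idx], levels = names(m))
  } else {
    lo <- m$min %||% -Inf; hi <- m$max %||% Inf
    plo <- pnorm(lo, m$mean, m$sd); phi <- pnorm(hi, m$mean, m$sd)
    qnorm(plo + pnorm(z) * (phi - plo), m$mean, m$sd)
  }
}

#' Generate a synthetic patient cohort
#'
#' Draws `spec$n` patients from the Gaussian copula(s) in the spec. With
#' several candidate dependence models, each patient is assigned to a
#' candidate with probability proportional to the candidate weights (uniform
#' when absent), so the cohort is a finite mixture over the candidate
#' copulas. Fully reproducible from `spec$seed`.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `synthetic_cohort`: a data frame with one row
#'   per patient, with attributes `model_weights` and `seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)
  vars <- names(spec$marginals)
  p <- length(vars)
  cands <- spec$candidates
  w <- attr(cands, "weights") %||% rep(1, length(cands))
  w <- w / sum(w)
  assign_idx <- if (length(cands) == 1L) rep(1L, spec$n)
                else sample(seq_along(cands), spec$n, replace = TRUE, prob = w)
  Z <- matrix(NA_real_, spec$n, p)
  for (ci in seq_along(cands)) {
    rows <- which(assign_idx == ci)
    if (length(rows))
      Z[rows, ] <- latent_draw(length(rows), cands[[ci]], p)
  }
  out <- data.frame(row.names = seq_len(spec$n))
  for (j in seq_len(p))
    out[[vars[j]]] <- transform_margin(Z[, j], spec$marginals[[j]], vars[j])
  attr(out, "model_weights") <- setNames(w, names(cands))
  attr(out, "seed") <- spec$seed
  class(out) <- c("synthetic_cohort", "data.frame")
  out
}

# P(lo1 < Z1 <= hi1, lo2 < Z2 <= hi2) for a standard bivariate normal with
# correlation rho, by one-dimensional quadrature.
bvn_rect <- function(lo1, hi1, lo2, hi2, rho) {
  if (abs(rho) < 1e-12)
    return((pnorm(hi1) - pnorm(lo1)) * (pnorm(hi2) - pnorm(lo2)))
  s <- sqrt(1 - rho^2)
  f <- function(z) dnorm(z) * (pnorm((hi2 - rho * z) / s) -
                               pnorm((lo2 - rho * z) / s))
  integrate(f, lower = max(lo1, -8), upper = min(hi1, 8),
            rel.tol = 1e-9)$value
}

# Joint cell probabilities of two categorical marginals under a Gaussian
# copula with latent correlation rho.
copula_cell_probs <- function(probs1, probs2, rho) {
  b1 <- qnorm(c(0, cumsum(probs1) / sum(probs1)))
  b2 <- qnorm(c(0, cumsum(probs2) / sum(probs2)))
  out <- matrix(0, length(probs1), length(probs2),
                dimnames = list(names(probs1), names(probs2)))
  for (i in seq_along(probs1))
    for (j in seq_along(probs2))
      out[i, j] <- bvn_rect(b1[i], b1[i + 1], b2[j], b2[j + 1], rho)
  out
}

#' Weight candidate dependence models against reference summaries
#'
#' Scores each candidate copula by the multinomial pseudo-likelihood of the
#' reference cohort's pairwise contingency tables under the candidate's
#' implied cell probabilities, converts to BIC (penalising each free latent
#' correlation), and returns normalised weights proportional to
#' `exp(-BIC / 2)` — a pseudo-likelihood realisation of Bayesian model
#' averaging over the candidate set.
#'
#' @param candidates Named list of candidate dependence models (correlation
#'   matrices, or `NULL` for independence).
#' @param reference A data frame of categorical reference observations (the
#'   summaries the synthesis must match).
#' @param marginals Marginals of the spec (category probabilities per
#'   variable).
#' @return Named numeric vector of weights summing to 1.
#' @export
weight_candidates <- function(candidates, reference, marginals) {
  if (!length(candidates)) stop_domain("need at least one candidate")
  vars <- names(marginals)
  cat_vars <- vars[vapply(marginals, is.numeric, TRUE)]
  if (length(cat_vars) < 2)
    stop_domain("pseudo-likelihood weighting needs at least two categorical variables")
  n_ref <- nrow(reference)
  score <- vapply(seq_along(candidates), function(ci) {
    R <- candidates[[ci]]
    ll <- 0; npar <- 0
    for (i in seq_along(cat_vars)[-length(cat_vars)]) {
      for (j in seq(i + 1, length(cat_vars))) {
        v1 <- cat_vars[i]; v2 <- cat_vars[j]
        rho <- if (is.null(R)) 0 else R[v1, v2]
        if (abs(rho) > 1e-12) npar <- npar + 1
        cells <- copula_cell_probs(marginals[[v1]], marginals[[v2]], rho)
        cells <- pmax(cells, 1e-12)
        obs <- table(factor(reference[[v1]], levels = names(marginals[[v1]])),
                     factor(reference[[v2]], levels = names(marginals[[v2]])))
        ll <- ll + sum(obs * log(cells))
      }
    }
    -2 * ll + npar * log(n_ref)        # BIC
  }, 0)
  if (all(!is.finite(score))) stop_domain("all candidates degenerate")
  w <- exp(-(score - min(score)) / 2)
  w <- w / sum(w)
  setNames(w, names(candidates) %||% paste0("cand", seq_along(candidates)))
}

#' Compare a synthetic cohort to its marginal targets
#'
#' For every category of every categorical target, computes the absolute
#' difference between the observed cohort frequency and the target, in
#' percentage points. Returns the maximum and the full per-category table;
#' large discrepancies in tiny cohorts are expected sampling noise and are
#' flagged, not errors.
#'
#' @param cohort A data frame (e.g. a `synthetic_cohort`).
#' @param marginals Named list of target category-probability vectors.
#' @return An object of class `marginal_comparison` with `max_discrepancy_pct`
#'   and `table` (variable, category, target, observed, discrepancy_pct).
#' @export
compare_to_targets <- function(cohort, marginals) {
  rows <- list()
  for (v in names(marginals)) {
    m <- marginals[[v]]
    if (!is.numeric(m)) next
    if (!v %in% names(cohort))
      stop_domain("variable '", v, "' not present in cohort")
    obs <- table(factor(cohort[[v]], levels = names(m))) / nrow(cohort)
    rows[[v]] <- data.frame(
      variable = v, category = names(m),
      target = unname(m), observed = as.numeric(obs),
      discrepancy_pct = abs(as.numeric(obs) - unname(m)) * 100,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  structure(list(max_discrepancy_pct = max(tab$discrepancy_pct), table = tab),
            class = "marginal_comparison")
}

#' @export
print.marginal_comparison <- function(x, ...) {
  cat(sprintf("<marginal_comparison> %d categories, max discrepancy %.2f%%\n",
              nrow(x$table), x$max_discrepancy_pct))
  invisible(x)
}
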