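# Pairwise study-overlap probabilities and inverse-overlap study weights.
#
# Two registry studies may describe the same patients. The overlap
# probability for a study pair is a weighted sum of four components:
# temporal overlap T (shared calendar years / minimum study duration),
# geographic overlap G (1 same country, 0.5 same continent, 0 otherwise),
# database overlap D (1 when the registry sets intersect, 0 otherwise) and
# criteria similarity C (Jaccard index of inclusion-criteria token sets):
#   O = 0.4*T + 0.2*G + 0.3*D + 0.1*C.
# Each study is then down-weighted by w_i = 1/(1 + sum_j O_ij).

OVERLAP_WEIGHTS_DEFAULT <- c(t = 0.4, g = 0.2, d = 0.3, c = 0.1)

#' Temporal overlap coefficient between two study periods
#'
#' Shared inclusive calendar years divided by the minimum of the two
#' inclusive study durations; 0 for disjoint periods, 1 when the shorter
#' period is fully contained in the longer.
#'
#' @param period_a,period_b Length-2 integer vectors `c(start, end)` of
#'   inclusive calendar years.
#' @return Coefficient in `[0, 1]`.
#' @export
temporal_overlap <- function(period_a, period_b) {
  check_period <- function(p) {
    if (length(p) != 2L || any(!is.finite(p)) || p[2] < p[1])
      stop_domain("invalid year range: ", paste(p, collapse = "-"))
  }
  check_period(period_a); check_period(period_b)
  common <- min(period_a[2], period_b[2]) - max(period_a[1], period_b[1]) + 1
  if (common <= 0) return(0)
  dur <- min(period_a[2] - period_a[1] + 1, period_b[2] - period_b[1] + 1)
  common / dur
}

load_continent_map <- function() {
  df <- read.csv(extdata_path("continent_map.csv"), stringsAsFactors = FALSE)
  setNames(df$continent, toupper(df$country))
}

#' Geographic overlap between two study records
#'
#' 1 when the country sets intersect, 0.5 when only the continent sets
#' intersect (continents from the packaged country-to-continent map),
#' 0 otherwise. Multi-country studies are compared as sets.
#'
#' @param record_a,record_b `study_record` objects.
#' @param continent_map Optional named vector country -> continent; defaults
#'   to the packaged map.
#' @return 0, 0.5 or 1.
#' @export
geographic_overlap <- function(record_a, record_b, continent_map = NULL) {
  continent_map <- continent_map %||% load_continent_map()
  ca <- record_a$country; cb <- record_b$country
  unknown <- setdiff(c(ca, cb), names(continent_map))
  if (length(unknown))
    stop_domain("country not in continent map: ",
                paste(unknown, collapse = ", "))
  if (length(intersect(ca, cb))) return(1)
  if (length(intersect(continent_map[ca], continent_map[cb]))) return(0.5)
  0
}

#' Database overlap between two study records
#'
#' 1 when the registry sets intersect (a multi-registry study overlaps any
#' study drawing on one of its registries), 0 otherwise.
#'
#' @param record_a,record_b `study_record` objects.
#' @return 0 or 1.
#' @export
database_overlap <- function(record_a, record_b) {
  as.numeric(length(intersect(record_a$database, record_b$database)) > 0)
}

#' Jaccard similarity of inclusion-criteria token sets
#'
#' @param criteria_a,criteria_b Non-empty character vectors of criteria
#'   tokens (here: histology-subtype labels).
#' @return `|A intersect B| / |A union B|` in `[0, 1]`.
#' @export
criteria_similarity <- function(criteria_a, criteria_b) {
  if (!length(criteria_a) || !length(criteria_b))
    stop_domain("criteria token sets must be non-empty")
  a <- unique(criteria_a); b <- unique(criteria_b)
  length(intersect(a, b)) / length(union(a, b))
}

#' Overlap probability from its four components
#'
#' @param t Temporal overlap in `[0, 1]`.
#' @param g Geographic overlap in `{0, 0.5, 1}`.
#' @param d Database overlap in `{0, 1}`.
#' @param c Criteria similarity in `[0, 1]`.
#' @param weights Component weights `(t, g, d, c)`; the defaults
#'   `c(0.4, 0.2, 0.3, 0.1)` are the primary analysis, overridable for
#'   sensitivity analyses.
#' @return Overlap probability `O` in `[0, 1]` (weighted sum).
#' @export
overlap_probability <- function(t, g, d, c, weights = OVERLAP_WEIGHTS_DEFAULT) {
  comp <- c(t = t, g = g, d = d, c = c)
  if (any(!is.finite(comp)) || any(comp < 0) || any(comp > 1))
    stop_domain("overlap components must lie in [0, 1]")
  if (length(weights) != 4L || any(weights < 0))
    stop_domain("need four non-negative component weights")
  sum(weights * comp)
}

#' Classify an overlap probability into a risk category
#'
#' high for `O >= 0.70`, medium for `0.30 <= O < 0.70`, low for
#' `0.10 <= O < 0.30`, none for `O < 0.10` (lower bounds closed).
#'
#' @param o Overlap probability/probabilities in `[0, 1]`.
#' @return Character vector of categories.
#' @export
classify_overlap <- function(o) {
  if (any(!is.finite(o)) || any(o < 0) || any(o > 1))
    stop_domain("overlap probability must lie in [0, 1]")
  ifelse(o >= 0.70, "high",
         ifelse(o >= 0.30, "medium",
                ifelse(o >= 0.10, "low", "none")))
}

#' Inverse-overlap study weights
#'
#' `w_i = 1 / (1 + sum_{j != i} O_ij)`: a study with no overlap keeps weight
#' exactly 1; heavily duplicated studies are shrunk towards 0 (never
#' reaching it), so all evidence is retained but double-counted patients
#' contribute less.
#'
#' @param o_matrix Symmetric overlap matrix with zero diagonal, entries in
#'   `[0, 1]`.
#' @return Numeric vector of weights in `(0, 1]`, named like the matrix rows.
#' @export
inverse_weights <- function(o_matrix) {
  o_matrix <- as.matrix(o_matrix)
  if (nrow(o_matrix) != ncol(o_matrix) ||
      max(abs(o_matrix - t(o_matrix))) > 1e-12 ||
      any(abs(diag(o_matrix)) > 1e-12) ||
      any(o_matrix < 0) || any(o_matrix > 1))
    stop_domain("o_matrix must be symmetric with zero diagonal and entries in [0, 1]")
  w <- 1 / (1 + rowSums(o_matrix))
  names(w) <- rownames(o_matrix)
  w
}

criteria_tokens_for <- function(record, criteria_map) {
  tok <- criteria_map[[record$study_id]]
  if (!is.null(tok) && length(tok)) return(tok)
  tok <- names(record$histology_props)
  if (length(tok)) {
    warning("no criteria tokens for study '", record$study_id,
            "'; falling back to histology-subtype set", call. = FALSE)
    return(tok)
  }
  warning("no criteria tokens or histology mix for study '", record$study_id,
          "'; assuming a mixed all-subtype cohort", call. = FALSE)
  HISTOLOGY_SUBTYPES
}

#' Assess the overlap structure of a study ecosystem
#'
#' Builds the full pairwise overlap matrix for a set of study records,
#' classifies each pair, assigns each study the category of its maximum
#' pairwise overlap (a conservative study-level summary), and computes
#' inverse-overlap weights. When no criteria tokens are supplied for a study
#' the histology-subtype set implied by its histology proportions is used
#' (with a warning); studies reporting no histology mix are treated as mixed
#' all-subtype cohorts.
#'
#' @param records List of at least two `study_record` objects.
#' @param criteria_map Optional named list study_id -> character vector of
#'   inclusion-criteria tokens.
#' @param weights Component weights passed to [overlap_probability()].
#' @param continent_map Optional country -> continent map.
#' @return An object of class `overlap_assessment` with elements
#'   `study_ids`, `o_matrix`, `components` (per-pair data frame with t/g/d/c),
#'   `pair_categories`, `study_category`, `weights` and
#'   `printed_labels` (transcribed labels kept side by side, never forced to
#'   agree with the computed categories).
#' @export
assess_ecosystem <- function(records, criteria_map = list(),
                             weights = OVERLAP_WEIGHTS_DEFAULT,
                             continent_map = NULL) {
  if (length(records) < 2L)
    stop_domain("need at least two study records")
  continent_map <- continent_map %||% load_continent_map()
  ids <- vapply(records, `[[`, "", "study_id")
  if (anyDuplicated(ids)) stop_domain("duplicate study ids")
  K <- length(records)
  tokens <- lapply(records, criteria_tokens_for, criteria_map = criteria_map)
  O <- matrix(0, K, K, dimnames = list(ids, ids))
  pairs <- list()
  for (i in seq_len(K - 1)) {
    for (j in seq(i + 1, K)) {
      a <- records[[i]]; b <- records[[j]]
      tij <- temporal_overlap(c(a$period_start, a$period_end),
                              c(b$period_start, b$period_end))
      gij <- geographic_overlap(a, b, continent_map)
      dij <- database_overlap(a, b)
      cij <- criteria_similarity(tokens[[i]], tokens[[j]])
      oij <- overlap_probability(tij, gij, dij, cij, weights)
      O[i, j] <- O[j, i] <- oij
      pairs[[length(pairs) + 1L]] <- data.frame(
        study_a = ids[i], study_b = ids[j],
        t = tij, g = gij, d = dij, c = cij, o = oij,
        category = classify_overlap(oij), stringsAsFactors = FALSE)
    }
  }
  components <- do.call(rbind, pairs)
  max_o <- apply(O, 1, max)
  structure(list(
    study_ids = ids,
    o_matrix = O,
    components = components,
    pair_categories = setNames(components$category,
                               paste(components$study_a, components$study_b,
                                     sep = ":")),
    study_category = setNames(classify_overlap(max_o), ids),
    weights = inverse_weights(O),
    printed_labels = setNames(
      vapply(records, function(r) as.character(r$printed_overlap_label), ""),
      ids)
  ), class = "overlap_assessment")
}

#' @export
print.overlap_assessment <- function(x, ...) {
  cat(sprintf("<overlap_assessment> %d studies, %d pairs\n",
              length(x$study_ids), nrow(x$components)))
  tab <- table(factor(x$study_category,
                      levels = c("high", "medium", "low", "none")))
  cat("  computed study categories:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  weight range: [", sprintf("%.3f", min(x$weights)), ", ",
      sprintf("%.3f", max(x$weights)), "]\n", sep = "")
  invisible(x)
}

#' Write overlap report and weight tables
#'
#' Emits `overlap_report.csv` (one row per study pair with the four
#' components, the overlap probability and its category) and `weights.csv`
#' (study_id, weight, computed category, printed label) into a directory.
#'
#' @param assessment An `overlap_assessment`.
#' @param dir Output directory (created if needed).
#' @return The two file paths, invisibly.
#' @export
write_overlap_report <- function(assessment, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep_path <- file.path(dir, "overlap_report.csv")
  w_path <- file.path(dir, "weights.csv")
  write.csv(assessment$components, rep_path, row.names = FALSE)
  write.csv(data.frame(study_id = assessment$study_ids,
                       weight = unname(assessment$weights),
                       computed_category = unname(assessment$study_category),
                       printed_label = unname(assessment$printed_labels),
                       stringsAsFactors = FALSE),
            w_path, row.names = FALSE)
  invisible(c(rep_path, w_path))
}
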