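# Study-record data model: one object per published registry study, mirroring
# the columns of the packaged study-summary table (see
# inst/extdata/study_table_schema.md).

HISTOLOGY_SUBTYPES <- c("MAC", "NMAC", "GCA", "SRCC", "NET", "MiNEN")
REGISTRIES <- c("SEER", "NCDB", "NCRAS", "PALGA", "INSTITUTIONAL")
OVERLAP_LABELS <- c("HIGH", "MEDIUM", "LOW", "NONE")

#' Construct a validated study record
#'
#' A study record captures one published registry study: its registry
#' source(s), country/countries, inclusive study period, sample size,
#' histology/stage/treatment mix and outcome summaries. Multi-registry
#' studies (e.g. a single publication spanning NCRAS and SEER) are stored as
#' one record whose `database` and `country` fields are sets.
#'
#' @param study_id Short unique label.
#' @param database Character vector of registry names (one or more of
#'   SEER, NCDB, NCRAS, PALGA, INSTITUTIONAL).
#' @param country Character vector of ISO 3166 alpha-2 country codes.
#' @param period_start,period_end Inclusive calendar years;
#'   `period_start <= period_end`. Duration is `end - start + 1`.
#' @param n_patients Positive integer sample size.
#' @param histology_props,stage_props,treatment_props Named numeric vectors
#'   of proportions in `[0, 1]` (fractions, not percent). Histology
#'   proportions may sum to at most 1.02 (tolerance for printed rounding).
#' @param institution_type,median_age_years,male_frac,median_os_months,five_year_os_pct
#'   Optional cohort summaries; `NA` means not reported, never zero.
#' @param printed_overlap_label Optional transcribed overlap-risk category
#'   (HIGH/MEDIUM/LOW/NONE); kept verbatim, never recomputed.
#' @param annotations Named list of unrecognised input columns, preserved.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, database, country, period_start, period_end,
                         n_patients,
                         histology_props = numeric(),
                         stage_props = numeric(),
                         treatment_props = numeric(),
                         institution_type = NA_character_,
                         median_age_years = NA_real_,
                         male_frac = NA_real_,
                         median_os_months = NA_real_,
                         five_year_os_pct = NA_real_,
                         printed_overlap_label = NA_character_,
                         annotations = list()) {
  if (!is.character(study_id) || length(study_id) != 1L || !nzchar(study_id))
    stop_domain("study_id must be a non-empty string")
  database <- toupper(as.character(database))
  bad <- setdiff(database, REGISTRIES)
  if (length(bad))
    stop_domain("unknown registry for study '", study_id, "': ",
                paste(bad, collapse = ", "))
  if (!is_scalar_number(period_start) || !is_scalar_number(period_end))
    stop_domain("study '", study_id, "': period bounds must be numeric years")
  if (period_end < period_start)
    stop_domain("study '", study_id, "': period_end (", period_end,
                ") precedes period_start (", period_start, ")")
  if (!is_scalar_number(n_patients) || n_patients < 1 ||
      n_patients != round(n_patients))
    stop_domain("study '", study_id, "': n_patients must be a positive integer")
  check_props <- function(p, what, max_sum = Inf) {
    p <- p[!is.na(p)]
    if (length(p) && (any(p < 0) || any(p > 1)))
      stop_domain("study '", study_id, "': ", what,
                  " proportions must lie in [0, 1]")
    if (length(p) && sum(p) > max_sum)
      stop_domain("study '", study_id, "': ", what,
                  " proportions sum to ", round(sum(p), 3),
                  " which exceeds ", max_sum)
    p
  }
  # summed-proportion check only applies when the full subtype breakdown is
  # reported; partial rows may overlap (e.g. a subgroup percentage printed
  # next to a two-way split)
  hist_sum_cap <- if (all(HISTOLOGY_SUBTYPES %in% names(histology_props)))
    1.02 else Inf
  histology_props <- check_props(histology_props, "histology",
                                 max_sum = hist_sum_cap)
  stage_props <- check_props(stage_props, "stage")
  treatment_props <- check_props(treatment_props, "treatment")
  if (!is.na(male_frac) && (male_frac < 0 || male_frac > 1))
    stop_domain("study '", study_id, "': male_frac must lie in [0, 1]")
  if (!is.na(printed_overlap_label) &&
      !toupper(printed_overlap_label) %in% OVERLAP_LABELS)
    stop_domain("study '", study_id, "': unknown overlap label '",
                printed_overlap_label, "'")
  structure(list(
    study_id = study_id,
    database = database,
    country = toupper(as.character(country)),
    period_start = as.integer(period_start),
    period_end = as.integer(period_end),
    n_patients = as.integer(n_patients),
    histology_props = histology_props,
    stage_props = stage_props,
    treatment_props = treatment_props,
    institution_type = institution_type,
    median_age_years = median_age_years,
    male_frac = male_frac,
    median_os_months = median_os_months,
    five_year_os_pct = five_year_os_pct,
    printed_overlap_label = if (is.na(printed_overlap_label)) NA_character_
                            else toupper(printed_overlap_label),
    annotations = annotations
  ), class = "study_record")
}

#' @export
print.study_record <- function(x, ...) {
  cat(sprintf("<study_record> %s  [%s; %s]  %d-%d  n=%d\n",
              x$study_id, paste(x$database, collapse = ";"),
              paste(x$country, collapse = ";"),
              x$period_start, x$period_end, x$n_patients))
  invisible(x)
}

#' Inclusive study duration in years
#' @param record A `study_record`.
#' @return Integer number of calendar years covered (end - start + 1).
#' @export
study_duration <- function(record) {
  record$period_end - record$period_start + 1L
}

parse_proportion <- function(x, row, col) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  if (!length(x) || is.na(x) || x == "") return(NA_real_)
  pct <- grepl("%$", x)
  v <- suppressWarnings(as.numeric(sub("%$", "", x)))
  if (is.na(v))
    stop_domain("row ", row, ": cannot parse proportion in column '", col,
                "': '", x, "'")
  if (pct) v / 100 else v
}

REQUIRED_STUDY_COLUMNS <- c("study_id", "database", "country",
                            "period_start", "period_end", "n_patients")

row_to_record <- function(row, i, extra_cols) {
  split_set <- function(x) strsplit(as.character(x), ";", fixed = TRUE)[[1]]
  num <- function(col) {
    v <- row[[col]]
    if (is.null(v) || is.na(v) || identical(v, "")) return(NA_real_)
    v <- suppressWarnings(as.numeric(v))
    if (is.na(v)) stop_domain("row ", i, ": malformed number in '", col, "'")
    v
  }
  props_from <- function(prefix) {
    cols <- grep(paste0("^", prefix), names(row), value = TRUE)
    if (!length(cols)) return(numeric())
    p <- vapply(cols, function(cl) parse_proportion(row[[cl]], i, cl), 0)
    names(p) <- sub(paste0("^", prefix), "", cols)
    p[!is.na(p)]
  }
  for (col in c("period_start", "period_end")) {
    v <- suppressWarnings(as.numeric(row[[col]]))
    if (is.na(v)) stop_domain("row ", i, ": malformed year in '", col, "'")
  }
  lbl <- row[["printed_overlap_label"]] %||% NA_character_
  if (!is.na(lbl) && lbl == "") lbl <- NA_character_
  ann <- as.list(row[extra_cols])
  rec <- study_record(
    study_id = as.character(row[["study_id"]]),
    database = split_set(row[["database"]]),
    country = split_set(row[["country"]]),
    period_start = as.numeric(row[["period_start"]]),
    period_end = as.numeric(row[["period_end"]]),
    n_patients = as.numeric(row[["n_patients"]]),
    histology_props = props_from("hist_"),
    stage_props = props_from("stage_"),
    treatment_props = props_from("treat_"),
    institution_type = as.character(row[["institution_type"]] %||% NA),
    median_age_years = num("median_age_years"),
    male_frac = if (!is.null(row[["male_frac"]]) && !is.na(row[["male_frac"]]) &&
                    row[["male_frac"]] != "")
                  parse_proportion(row[["male_frac"]], i, "male_frac")
                else NA_real_,
    median_os_months = num("median_os_months"),
    five_year_os_pct = num("five_year_os_pct"),
    printed_overlap_label = as.character(lbl),
    annotations = ann
  )
  rec
}

#' Read a study-summary table
#'
#' Reads a CSV or JSON study-summary table (one row per study; see the
#' packaged schema file `study_table_schema.md`) into a list of validated
#' [study_record()] objects. Percent-formatted proportions are converted to
#' fractions; unknown columns are preserved as per-record annotations.
#'
#' @param path Path to the file.
#' @param format "csv" or "json"; guessed from the file extension by default.
#' @return List of `study_record` objects.
#' @export
read_study_table <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- if (format == "csv") {
    read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(REQUIRED_STUDY_COLUMNS, names(df))
  if (length(missing_cols))
    stop_domain("missing required field(s): ",
                paste(missing_cols, collapse = ", "))
  known <- c(REQUIRED_STUDY_COLUMNS, "institution_type", "median_age_years",
             "male_frac", "median_os_months", "five_year_os_pct",
             "printed_overlap_label")
  extra <- setdiff(names(df),
                   c(known, grep("^(hist|stage|treat)_", names(df), value = TRUE)))
  lapply(seq_len(nrow(df)), function(i) row_to_record(df[i, , drop = FALSE], i, extra))
}

records_to_frame <- function(records) {
  prop_cols <- function(field, prefix) {
    keys <- unique(unlist(lapply(records, function(r) names(r[[field]]))))
    out <- lapply(keys, function(k)
      vapply(records, function(r) unname(r[[field]][k]), 0))
    names(out) <- paste0(prefix, keys)
    out
  }
  base <- data.frame(
    study_id = vapply(records, `[[`, "", "study_id"),
    database = vapply(records, function(r) paste(r$database, collapse = ";"), ""),
    country = vapply(records, function(r) paste(r$country, collapse = ";"), ""),
    period_start = vapply(records, `[[`, 0L, "period_start"),
    period_end = vapply(records, `[[`, 0L, "period_end"),
    n_patients = vapply(records, `[[`, 0L, "n_patients"),
    institution_type = vapply(records, function(r) as.character(r$institution_type), ""),
    median_age_years = vapply(records, `[[`, 0, "median_age_years"),
    male_frac = vapply(records, `[[`, 0, "male_frac"),
    stringsAsFactors = FALSE)
  extras <- c(prop_cols("histology_props", "hist_"),
              prop_cols("stage_props", "stage_"),
              prop_cols("treatment_props", "treat_"))
  for (nm in names(extras)) base[[nm]] <- extras[[nm]]
  base$median_os_months <- vapply(records, `[[`, 0, "median_os_months")
  base$five_year_os_pct <- vapply(records, `[[`, 0, "five_year_os_pct")
  base$printed_overlap_label <-
    vapply(records, function(r) as.character(r$printed_overlap_label), "")
  base
}

#' Write a study-summary table
#'
#' Inverse of [read_study_table()]: serialises a list of study records to CSV
#' or JSON with the schema column names, so that write-then-read round-trips.
#'
#' @param records List of `study_record` objects.
#' @param path Output path.
#' @param format "csv" or "json"; guessed from the extension by default.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- records_to_frame(records)
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE, na = "")
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", na = "null", digits = NA)
  }
  invisible(path)
}

#' Construct an effect estimate from a hazard ratio and its 95\% CI
#'
#' Recovers the log hazard ratio and its standard error from a printed point
#' estimate and confidence interval, using the standard meta-analytic
#' relation `se = (log(ci_high) - log(ci_low)) / (2 * 1.96)`. A degenerate
#' point interval (`ci_low == ci_high`) yields `se = 0` and is flagged.
#'
#' @param hr Hazard ratio, `> 0`.
#' @param ci_low,ci_high 95\% CI bounds with `0 < ci_low <= hr <= ci_high`.
#' @param study_id Optional study label.
#' @param histology_group Optional subgroup label.
#' @return An object of class `effect_estimate` with fields `hr`, `ci_low`,
#'   `ci_high`, `log_hr`, `se_log_hr`, `degenerate`.
#' @export
effect_from_ci <- function(hr, ci_low, ci_high, study_id = NA_character_,
                           histology_group = NA_character_) {
  if (!is_scalar_number(hr) || hr <= 0 ||
      !is_scalar_number(ci_low) || ci_low <= 0 ||
      !is_scalar_number(ci_high) || ci_high <= 0)
    stop_domain("hazard ratio and CI bounds must be positive numbers")
  if (ci_low > hr || hr > ci_high)
    stop_domain("require ci_low <= hr <= ci_high (got ", ci_low, ", ", hr,
                ", ", ci_high, ")")
  se <- (log(ci_high) - log(ci_low)) / (2 * qnorm(0.975))
  structure(list(
    study_id = study_id,
    hr = hr, ci_low = ci_low, ci_high = ci_high,
    log_hr = log(hr), se_log_hr = se,
    degenerate = se == 0,
    histology_group = histology_group
  ), class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s  HR %.3f (%.3f-%.3f)  logHR %.4f se %.4f\n",
              x$study_id, x$hr, x$ci_low, x$ci_high, x$log_hr, x$se_log_hr))
  invisible(x)
}

#' Construct a rate pair
#'
#' A pair of outcome proportions (exposed vs reference) used for fold-ratio,
#' odds-ratio, absolute-risk-reduction and number-needed-to-treat
#' calculations. For ratio operations both proportions must lie strictly
#' inside `(0, 1)`.
#'
#' @param label Description of the comparison.
#' @param p_exposed,p_reference Proportions in `(0, 1)`.
#' @param n_exposed,n_reference Optional group sizes.
#' @return An object of class `rate_pair`.
#' @export
rate_pair <- function(label, p_exposed, p_reference,
                      n_exposed = NA_integer_, n_reference = NA_integer_) {
  if (!is_scalar_number(p_exposed) || !is_scalar_number(p_reference) ||
      p_exposed <= 0 || p_exposed >= 1 || p_reference <= 0 || p_reference >= 1)
    stop_domain("rate pair '", label,
                "': proportions must lie strictly inside (0, 1)")
  structure(list(label = label, p_exposed = p_exposed,
                 p_reference = p_reference,
                 n_exposed = n_exposed, n_reference = n_reference),
            class = "rate_pair")
}

#' Load a packaged fixture
#'
#' The package ships the summary tables of an 18-study appendiceal-neoplasm
#' evidence base as plain-text fixtures, so every pipeline stage runs without
#' network access:
#' \describe{
#'   \item{table1}{18 study records (baseline characteristics, periods,
#'     registries, histology/stage/treatment mixes, printed overlap labels).}
#'   \item{table3}{Seven per-study hazard-ratio effect estimates; the printed
#'     pooled reference rows are attached as `attr(, "reference")` and are
#'     never fed back into pooling.}
#'   \item{table4_rates}{Rate pairs behind the printed numbers needed to
#'     treat.}
#'   \item{table5_rates}{Perioperative quality-metric rate pairs (margin
#'     status, race, surgical extent).}
#'   \item{table4_effects}{Treatment-scenario hazard ratios (e.g. HIPEC 0.13,
#'     complete resection 0.30) used for E-value sensitivity analysis.}
#' }
#'
#' @param name One of "table1", "table3", "table4_rates", "table5_rates",
#'   "table4_effects".
#' @return A typed collection as described above.
#' @export
load_fixture <- function(name) {
  switch(name,
    table1 = read_study_table(extdata_path("table1_studies.csv")),
    table3 = {
      df <- read.csv(extdata_path("table3_effects.csv"), stringsAsFactors = FALSE)
      eff <- lapply(seq_len(nrow(df)), function(i)
        effect_from_ci(df$hr[i], df$ci_low[i], df$ci_high[i],
                       study_id = df$study_id[i],
                       histology_group = df$histology_group[i]))
      names(eff) <- df$study_id
      attr(eff, "reference") <-
        read.csv(extdata_path("table3_reference.csv"), stringsAsFactors = FALSE)
      eff
    },
    table4_rates = load_rate_fixture("table4_rates.csv"),
    table5_rates = load_rate_fixture("table5_rates.csv"),
    table4_effects =
      read.csv(extdata_path("table4_effects.csv"), stringsAsFactors = FALSE),
    stop_domain("unknown fixture name: '", name, "'")
  )
}

load_rate_fixture <- function(file) {
  df <- read.csv(extdata_path(file), stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i)
    rate_pair(df$label[i], df$p_exposed[i], df$p_reference[i]))
  names(out) <- df$label
  attr(out, "printed") <- df
  out
}
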