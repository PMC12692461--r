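# Small in-code builders shared across test files.

make_record <- function(id = "s1", db = "SEER", country = "US",
                        start = 2000, end = 2010, n = 100,
                        hist = c(MAC = 0.5, NMAC = 0.5), ...) {
  study_record(study_id = id, database = db, country = country,
               period_start = start, period_end = end, n_patients = n,
               histology_props = hist, ...)
}

make_effect <- function(hr, se, id = "s1") {
  effect_from_ci(hr, exp(log(hr) - qnorm(0.975) * se),
                 exp(log(hr) + qnorm(0.975) * se), study_id = id)
}

# effects with equal standard errors, handy for closed-form checks
equal_se_effects <- function(hrs, se = 0.1) {
  lapply(seq_along(hrs), function(i)
    make_effect(hrs[i], se, id = paste0("s", i)))
}

table3_effects <- function() load_fixture("table3")

load_continent_map_test <- function() {
  df <- read.csv(system.file("extdata", "continent_map.csv",
                             package = "registrysynth"))
  setNames(df$continent, df$country)
}

table1_assessment <- function() {
  suppressWarnings(assess_ecosystem(load_fixture("table1")))
}
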