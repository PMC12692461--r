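# Study-summary table schema

One row per published study. CSV and JSON inputs use identical field names.

Required columns:

- `study_id` — short unique label.
- `database` — registry name(s); multi-registry studies separate names with
  `;` (e.g. `NCRAS;SEER`). Recognised registries: SEER, NCDB, NCRAS, PALGA,
  INSTITUTIONAL.
- `country` — ISO 3166 alpha-2 code(s), `;`-separated for multi-country
  cohorts. Continents are derived from `continent_map.csv`.
- `period_start`, `period_end` — inclusive calendar years. Duration is
  `period_end - period_start + 1`.
- `n_patients` — positive integer.

Optional columns:

- `institution_type` — free text.
- `median_age_years`, `male_frac` — cohort summaries; `male_frac` in [0,1].
- `hist_<SUBTYPE>` — histology proportions in [0,1]; recognised subtypes:
  MAC, NMAC, GCA, SRCC, NET, MiNEN. Values summing to more than 1.02 when
  all subtypes are reported are rejected.
- `stage_<GROUP>` — stage-group proportions (`early`, `regional`, `distant`).
- `treat_<MODALITY>` — treatment proportions (`rhc`, `appendectomy`,
  `chemo`, `hipec`).
- `median_os_months`, `five_year_os_pct` — outcome summaries as printed.
- `printed_overlap_label` — transcribed overlap-risk category
  (HIGH | MEDIUM | LOW | NONE), kept verbatim and never recomputed.

Percent-formatted strings ("52.8%") are parsed by stripping the sign and
dividing by 100. Missing optional values are stored as absent (NA), never as
zero. Unknown columns are preserved as annotations.
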