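study_id,database,country,period_start,period_end,n_patients,institution_type,median_age_years,male_frac,hist_MAC,hist_NMAC,hist_GCA,hist_SRCC,hist_NET,hist_MiNEN,stage_early,stage_regional,stage_distant,treat_rhc,treat_appendectomy,treat_chemo,treat_hipec,median_os_months,five_year_os_pct,printed_overlap_label
elasmar2024,NCRAS;SEER,GB;US,1995,2020,2701,Population-based,58.7,0.495,,,1.0,,,,0.716,0.077,0.057,0.71,0.29,0.158,,,73.8,LOW
baron2024,NCDB,US,2004,2019,6800,Academic/Community/Integrated,61,0.528,0.422,0.504,,0.074,,,0.782,0.218,,0.715,0.285,0.373,,54.0,,HIGH
emile2024,NCDB,US,2005,2019,2607,,61.6,0.516,0.46,0.453,,0.087,,,0.85,0.15,,0.617,,0.394,,126.3,58.4,HIGH
freudenberger2023,NCDB,US,2006,2018,2532,Academic/Community/Integrated,57,0.476,,,,,,,,,,,,,1.0,136.3,,HIGH
marks2023,NCDB,US,2004,2017,18216,Academic/Community/Integrated,,,0.34,0.24,0.11,,0.31,,,,,0.60,0.40,,,,,MEDIUM
wang2023,SEER,US,2004,2015,2891,Population-based,62,0.459,0.256,0.214,,0.056,0.473,,0.457,0.299,0.244,,,0.305,,65,51.9,MEDIUM
wang2021,SEER,US,1998,2016,8733,Population-based,57,0.452,0.324,0.202,0.125,0.066,0.239,,,,,0.505,0.441,0.318,,,65.8,MEDIUM
zheng2020,SEER,US,2004,2016,315,Population-based,57,0.502,,,,,,1.0,0.276,0.387,0.337,0.622,0.327,,,,57.4,LOW
byrne2019,NCDB,US,2004,2014,18055,Academic/Community/Integrated,54.6,0.48,0.818,0.182,,,0.07,,0.148,0.029,0.691,,,,0.0771,,65.6,HIGH
yan2019,SEER,US,1973,2015,3237,Population-based,57.7,0.437,1.0,,,,,,0.135,,0.464,0.36,0.252,0.47,,80,56.2,MEDIUM
shaib2017,SEER,US,1973,2011,2733,Population-based,59.6,0.454,1.0,,,,,,0.263,0.205,0.532,0.706,0.022,,,42,,MEDIUM
xie2016,SEER,US,2004,2013,1404,Population-based,61.3,0.505,0.478,0.513,,,,,,,,0.596,,,,,64,LOW
asare2016,NCDB,US,1985,2006,11871,Population-based,57.9,0.461,0.503,0.405,,0.092,,,0.391,0.089,0.52,,,0.518,,76.8,53.6,MEDIUM
ansari2016,INSTITUTIONAL,GB,1994,2014,1000,Single center (tertiary),56,0.34,,,,,,,,,,,,,1.0,103.4,87.4,NONE
marmor2015,SEER,US,2000,2009,4765,Population-based,58,0.484,0.38,0.27,,0.07,0.28,,0.26,0.39,0.35,,,,,,77,HIGH
turaga2012,SEER,US,1973,2007,5655,Population-based,46,0.47,0.37,0.27,0.19,0.055,0.11,,,,,0.39,,,,85,93,HIGH
smeenk2008,PALGA,NL,1995,2005,1482,Population-based,61,0.41,0.387,0.306,,,,,,,,,,,,,,NONE
mccusker2002,SEER,US,1973,1998,1645,Population-based,60,0.49,0.373,0.25,0.138,0.043,0.197,,0.37,,0.63,0.52,,,,,,HIGH
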