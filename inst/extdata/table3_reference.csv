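label,hr,ci_low,ci_high,n_patients,five_year_os_pct,note
overall_pooled,0.723,0.591,0.884,38539,61.3,all histological types combined
mixed_histologies_pooled,0.748,0.591,0.948,32286,58.1,pooled from 4 adenocarcinoma studies
gca_subtype,0.383,0.355,0.413,2701,76.7,single study
minen_subtype,0.801,0.642,0.999,315,57.4,single study
mac_subtype,0.831,0.776,0.891,3237,56.2,single study
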