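study_id,hr,ci_low,ci_high,histology_group,n_patients
elasmar2024,0.383,0.355,0.413,GCA,2701
emile2024,0.776,0.719,0.838,Mixed adenocarcinoma,2607
wang2023,0.946,0.880,1.018,Mixed histologies,2891
wang2021,0.819,0.785,0.854,Mixed histologies,8733
zheng2020,0.801,0.642,0.999,MiNEN,315
byrne2019,0.608,0.591,0.626,Mixed CRS/HIPEC,18055
yan2019,0.831,0.776,0.891,MAC,3237
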