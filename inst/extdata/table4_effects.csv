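scenario,hr,ci_low,ci_high,comparison
r0_resection,0.30,0.25,0.37,complete (R0) vs incomplete (R1/R2) resection
hemicolectomy_vs_partial,0.64,0.52,0.79,right hemicolectomy vs partial colectomy
rhc_vs_appendectomy,1.56,1.12,2.17,right hemicolectomy vs appendectomy
race_nhb_vs_nhw,1.28,1.15,1.43,CRS/HIPEC outcomes NHB vs NHW
hipec_vs_systemic,0.13,0.10,0.17,CRS/HIPEC vs standard care in stage IV
chemo_mac,0.85,0.76,0.95,chemotherapy benefit in MAC
chemo_nmac,0.92,0.84,1.01,chemotherapy benefit in NMAC
chemo_srcc,1.15,0.98,1.35,chemotherapy benefit in SRCC
gca_surgery,0.75,0.65,0.87,surgical approach for GCA
net_surgery,0.25,0.18,0.35,size-based surgical approach for NET
srcc_aggressive,1.85,1.45,2.36,aggressive vs conservative surgery in SRCC
elderly_extensive,2.15,1.75,2.64,extensive vs limited surgery in elderly
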