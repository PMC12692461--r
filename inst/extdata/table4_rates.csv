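label,p_exposed,p_reference,exposed_label,reference_label,printed_nnt
r0_resection_30day_mortality,0.011,0.037,complete (R0) resection,incomplete (R1/R2) resection,38
hemicolectomy_30day_mortality,0.018,0.028,right hemicolectomy,partial colectomy,100
ccrs_hipec_5yr_os,0.874,0.392,complete cytoreduction + HIPEC,maximum tolerated dose,2
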