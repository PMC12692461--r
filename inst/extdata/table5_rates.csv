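label,p_exposed,p_reference,exposed_label,reference_label,printed_fold
positive_margin_30day_mortality,0.037,0.011,positive resection margin,negative resection margin,3.4
positive_margin_90day_mortality,0.069,0.017,positive resection margin,negative resection margin,4.1
nhb_hipec_30day_mortality,0.022,0.009,non-Hispanic Black,non-Hispanic White,2.4
nhb_hipec_readmission,0.075,0.062,non-Hispanic Black,non-Hispanic White,
rhc_vs_appendectomy_30day_mortality,0.014,0.009,right hemicolectomy,appendectomy,
ccrs_vs_mtd_30day_mortality,0.008,0.017,complete cytoreductive surgery,maximum tolerated dose,
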