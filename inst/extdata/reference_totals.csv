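label,value
abstract_total_patients,67001
model_table_total_patients,67428
survival_modeling_n,38539
quality_metrics_n,29749
causal_inference_n,45127
n_studies,18
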