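variable,level,n_sample,benchmark_pct,unweighted_pct,unweighted_ci_lo,unweighted_ci_hi,diff_unweighted_pct,weighted_pct,weighted_ci_lo,weighted_ci_hi,diff_weighted_pct
hypertension,Yes,32287,31.20,32.16,31.87,32.45,0.96,29.20,28.82,29.57,2.00
coronary_artery_disease,Yes,4585,4.70,4.57,4.44,4.70,0.13,4.03,3.88,4.18,0.67
diabetes,Yes,11712,9.30,11.67,11.47,11.87,2.37,10.99,10.74,11.25,1.69
alcohol_use,Yes,96095,86.60,95.72,95.59,95.84,9.12,94.23,94.00,94.45,7.63
ever_smoker,Yes,35282,16.10,35.14,34.85,35.44,19.04,30.13,29.76,30.51,14.03
health_insurance,Yes,95119,88.90,94.75,94.61,94.88,5.85,93.27,93.03,93.50,4.37
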