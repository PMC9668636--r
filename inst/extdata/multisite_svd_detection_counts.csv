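cohort,stage,tp,fp
UT,large_effect,56,576
ZO,large_effect,105,588
HK,large_effect,30,350
SI,large_effect,63,270
pooled_raw,large_effect,231,2040
pooled_harmonized,large_effect,67,1065
UT,surviving_threshold,54,30
ZO,surviving_threshold,100,83
HK,surviving_threshold,23,38
SI,surviving_threshold,56,38
pooled_raw,surviving_threshold,206,88
pooled_harmonized,surviving_threshold,62,11
UT,surviving_fdr,17,8
ZO,surviving_fdr,0,0
HK,surviving_fdr,0,0
SI,surviving_fdr,0,0
pooled_raw,surviving_fdr,140,24
pooled_harmonized,surviving_fdr,37,1
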