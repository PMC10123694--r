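gender,poor_upper,fair_upper,source
0,41.7,45.3,"synthetic approximate transcription of ACSM-style percentile norms, men 20-29; replace with your reference table"
1,33.8,37.5,"synthetic approximate transcription of ACSM-style percentile norms, women 20-29; replace with your reference table"
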