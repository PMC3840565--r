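statistic	value
n_scaffolds	62461
n50_scaffolds_bp	3016365
total_span_mb	832
n_anchored	41061
n50_anchored_bp	1935203
anchored_length_mb	517
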