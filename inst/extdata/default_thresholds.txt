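# normalized-alignment-score thresholds
score_threshold = 0.6
orientation_threshold = 0.5
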