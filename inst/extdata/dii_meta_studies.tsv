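LABEL	OR	CI_LOW	CI_HIGH
Luo et al. 2024	1.14	1.01	1.29
Jiang et al. 2024	1.10	1.01	1.19
Wu et al. 2024	1.44	1.08	1.91
Cheng et al. 2025	1.52	1.19	1.93
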