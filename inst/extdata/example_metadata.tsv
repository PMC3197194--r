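sample_id	group
high_001	high
high_002	high
high_003	high
high_004	high
low_001	low
low_002	low
low_003	low
low_004	low
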