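quartile,n_cases,n_controls
1,89,77358
2,101,77529
3,106,77701
4,129,77588
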