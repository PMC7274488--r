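characteristic,group,count,denominator
female,benign_cases,1492,1812
female,cancer_cases,316,425
obese,benign_cases,471,1812
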