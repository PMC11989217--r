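category,true_moisture
1,0.7799
5,0.7231
9,0.597
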