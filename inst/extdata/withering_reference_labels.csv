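class_index,moisture
0,0.7843
1,0.7714
2,0.763
3,0.7501
4,0.699
5,0.6654
6,0.6372
7,0.5671
8,0.5177
9,0.4863
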