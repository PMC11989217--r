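class_index,cat1,cat5,cat9
0,0.91888142,0,0
1,0.08109235,0.00000007,0
2,0.00002619,0.00961427,0
3,0.00000001,0.41952419,0
4,0,0.57085168,0.00000004
5,0,0.00000980,0.00098720
6,0,0,0.53591472
7,0,0,0.45765832
8,0,0,0.00543968
9,0,0,0.00000003
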