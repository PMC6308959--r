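run,device,reference
1,36.89,36.3
2,36.75,36.4
3,36.33,36.4
4,36.85,36.4
5,36.19,36.5
6,36.41,37
7,36.59,36.4
8,36.61,36.5
9,36.71,36.4
10,36.81,36.4
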