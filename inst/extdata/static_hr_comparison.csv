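run,device,reference
1,74,81
2,80,78
3,75,80
4,77,75
5,73,80
6,91,88
7,93,91
8,85,78
9,84,81
10,81,80
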