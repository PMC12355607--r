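n,alpha_05,alpha_01
5,1.000,NA
6,0.886,1.000
7,0.786,0.929
8,0.738,0.881
9,0.700,0.833
10,0.648,0.794
11,0.618,0.755
12,0.587,0.727
13,0.560,0.703
14,0.538,0.679
15,0.521,0.654
16,0.503,0.635
17,0.488,0.618
18,0.472,0.600
19,0.460,0.584
20,0.447,0.570
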