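pc,eigenvalue
1,9.460e-05
2,2.9085e-07
3,8.0030e-08
4,3.8928e-08
5,1.9657e-08
6,3.7732e-09
7,8.2980e-10
8,4.9310e-10
9,1.8386e-10
10,8.4961e-11
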