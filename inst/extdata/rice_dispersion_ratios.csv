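i,j,lambda
1,2,0.1441
1,3,0.1855
1,4,0.1687
1,5,0.1254
1,6,0.1709
1,7,0.1877
1,8,0.1552
1,9,0.1407
1,10,0.1569
2,3,0.5154
2,4,0.4351
2,5,0.3127
2,6,0.3563
2,7,0.4921
2,8,0.4793
2,9,0.4642
2,10,0.4855
3,4,0.6940
3,5,0.5111
3,6,0.5122
3,7,0.7981
3,8,0.7470
3,9,0.7650
3,10,0.7846
4,5,0.4195
4,6,0.5632
4,7,0.6848
4,8,0.7219
4,9,0.7435
4,10,0.7360
5,6,0.3298
5,7,0.4631
5,8,0.4728
5,9,0.4979
5,10,0.5204
6,7,0.7126
6,8,0.6931
6,9,0.7189
6,10,0.6781
7,8,0.9207
7,9,0.9848
7,10,0.8886
8,9,0.9332
8,10,0.9511
9,10,0.9562
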