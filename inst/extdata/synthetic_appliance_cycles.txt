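5.636
0.028
1.317
0.155
0.992
0.002
0.190
1.523
1.447
1.168
1.852
0.485
5.411
0.213
0.506
4.301
0.357
2.990
0.513
0.171
0.272
5.317
4.117
5.003
0.860
0.437
1.004
0.156
1.028
0.321
2.552
1.301
1.323
7.593
1.260
3.741
1.249
0.326
0.721
1.215
0.110
3.093
0.115
2.939
1.771
0.230
1.062
3.721
0.960
0.486
0.411
4.332
1.299
6.961
0.060
0.321
0.769
1.955
2.545
1.336
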