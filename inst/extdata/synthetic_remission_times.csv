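"time"
1.737
3.349
14.49
13.11
7.677
1.538
1.35
21.095
7.785
51.811
4.471
2.759
10.25
7.882
2.981
5.885
3.431
30.018
3.635
0.5
10.96
18.773
4.164
9.734
3.986
5.1
42.02
5.816
3.903
1.532
6.926
2.868
10.519
1.798
7.92
1.061
7.713
4.152
3.951
9.516
13.145
6.464
14.806
6.949
2.383
11.149
2.495
4.596
1.32
11.97
1.844
11.583
3.559
24.473
36.848
7.293
29.053
3.605
0.869
5.736
2.059
6.738
3.654
20.023
5.207
33.816
3.157
1.553
3.407
3.854
2.276
5.761
5.574
12.583
4.77
0.941
1.77
85.991
4.588
4.679
13.458
4.006
6.894
9.203
19.266
27.919
9.181
3.585
2.64
0.981
11.156
0.328
2.456
5.494
15.912
2.01
20.682
28.897
3.368
14.787
4.884
2.806
5.281
4.265
16.428
2.161
6.016
0.716
3.615
5.204
65.471
28.304
2.897
4.71
1.533
3.527
7.301
31.866
9.047
1.608
8.349
1.343
2.113
2.502
0.849
59.444
1.785
27.299
6.702
2.518
4.233
29.924
26.794
2.82
3.985
1.503
7.013
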