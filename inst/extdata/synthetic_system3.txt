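27.983
39.497
82.621
69.353
52.737
34.786
27.100
38.219
29.097
23.386
24.265
51.276
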