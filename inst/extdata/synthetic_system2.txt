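102.961
19.975
45.543
89.321
73.818
64.025
113.670
55.125
45.698
199.322
37.815
54.725
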