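213.109
108.439
28.194
115.309
111.719
399.934
262.829
27.825
281.437
41.577
47.630
261.972
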