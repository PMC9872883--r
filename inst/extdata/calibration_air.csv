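1.0000,0.0092,0.0094,0.0198
0.0093,0.9910,0.0092,0.0197
0.0094,0.0091,0.9920,0.0197
0.0197,0.0199,0.0200,0.9810
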