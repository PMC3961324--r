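# the same six data points hard-labeled by the larger of the two weights
score	label
2.54	fg
2.37	fg
1.56	bg
1.35	bg
0.06	fg
-1.08	bg
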