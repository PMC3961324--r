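# six scored data points with soft labels (foreground/background weights)
score	w_fg	w_bg
2.54	0.9	0.1
2.37	0.92	0.08
1.56	0.22	0.78
1.35	0.07	0.93
0.06	0.67	0.33
-1.08	0.09	0.91
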