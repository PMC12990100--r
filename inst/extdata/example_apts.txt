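# q_tot=1 n=4
1 Na 1.02 0 0 0 1.02 0 0 0 1.02
2 O -0.62 0.05 0 0.02 -0.66 0.01 0 0.03 -0.7
3 H 0.31 -0.02 0 0.01 0.34 0 0 0 0.31
4 H 0.35 0 0.01 0 0.3 0 0.02 0 0.33
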