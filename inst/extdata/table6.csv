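parameter,threshold,modelA_comfa,modelA_comsia,modelB_comfa,modelB_comsia
q2,>0.5,0.622,0.723,0.810,0.719
r2,>0.6,0.974,0.994,0.884,0.911
r0_sq_primed,close to r2,0.794,0.980,0.808,0.909
k_primed,0.85-1.15,1.098,0.983,0.949,0.990
r2_gap_primed,<0.1,0.185,0.014,0.086,0.001
rm2,>0.5,0.561,0.875,0.640,0.880
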