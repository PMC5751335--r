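model,assay,SD,PRESS,r2_pred
CoMFA-E,1e-9,0.7219,0.1798,0.751
CoMSIA-EA,1e-9,0.0699,0.0038,0.946
CoMFA-SE,1e-10,0.6282,0.1446,0.770
CoMSIA-EHA,1e-10,0.6269,0.0484,0.923
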