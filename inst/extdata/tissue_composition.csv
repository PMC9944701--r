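tissue,f_ew,f_iw,f_nl,f_np,ap_mg_g,ph
adipose,0.135,0.017,0.790,0.0016,0.40,7.0
muscle,0.118,0.630,0.0238,0.0072,1.53,7.0
gi,0.282,0.475,0.0487,0.0163,2.41,7.0
spleen,0.207,0.579,0.0077,0.0136,3.18,7.0
pancreas,0.120,0.664,0.0403,0.0090,0.405,7.0
blood_cells,0,0.603,0.0017,0.0029,0.50,7.22
plasma,0.945,0,0.0023,0.0013,0,7.4
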