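organ,volume_L,flow_L_per_min
whole_body,18.09524,3.4
arterial_blood,0.41038,
venous_blood,1.03962,
lung,0.11905,3.4
heart_vascular,0.01214,0.136
heart_extravascular,0.06881,
heart_chambers,0.13136,
brain_vascular,0.05152,0.612
muscle,5.38462,0.408
liver,0.54286,0.867
hepatic_artery,,0.221
gallbladder,0.018,
gi_tissue,0.43269,0.51
spleen,0.04808,0.102
pancreas,0.03365,0.034
kidney_vascular,0.01917,0.578
kidney_extravascular,0.08559,
adipose,5.97826,0.17
thyroid,0.00324,0.051
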