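organ,volume_L,flow_L_per_min
whole_body,9.52381,1.2
arterial_blood,0.22075,
venous_blood,0.55925,
lung,0.07619,1.2
heart_vascular,0.00714,0.048
heart_extravascular,0.04048,
heart_chambers,0.07727,
brain_vascular,0.03931,0.264
muscle,1.82692,0.12
liver,0.31429,0.306
hepatic_artery,,0.078
gallbladder,0.01,
gi_tissue,0.21154,0.18
spleen,0.02788,0.036
pancreas,0.01923,0.012
kidney_vascular,0.0122,0.18
kidney_extravascular,0.05447,
adipose,4.13043,0.06
thyroid,0.00171,0.018
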