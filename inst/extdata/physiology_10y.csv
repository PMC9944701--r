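organ,volume_L,flow_L_per_min
whole_body,30.47619,5
arterial_blood,0.67925,
venous_blood,1.72075,
lung,0.2,5
heart_vascular,0.02,0.2
heart_extravascular,0.11333,
heart_chambers,0.21636,
brain_vascular,0.05421,0.75
muscle,10.57692,0.7
liver,0.79048,1.275
hepatic_artery,,0.325
gallbladder,0.03,
gi_tissue,0.71154,0.75
spleen,0.07692,0.15
pancreas,0.05769,0.05
kidney_vascular,0.03137,0.9
kidney_extravascular,0.14006,
adipose,9.34783,0.25
thyroid,0.00752,0.075
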