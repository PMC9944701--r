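organ,volume_L,flow_L_per_min
whole_body,69.52381,6.5
arterial_blood,1.5,
venous_blood,3.8,
lung,0.47619,6.5
heart_vascular,0.04714,0.26
heart_extravascular,0.26714,
heart_chambers,0.51,
brain_vascular,0.06,0.78
muscle,27.88462,1.105
liver,1.71429,1.6575
hepatic_artery,,0.4225
gallbladder,0.058,
gi_tissue,1.125,0.975
spleen,0.14423,0.195
pancreas,0.13462,0.065
kidney_vascular,0.05403,1.235
kidney_extravascular,0.24121,
adipose,19.78261,0.325
thyroid,0.01905,0.0975
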