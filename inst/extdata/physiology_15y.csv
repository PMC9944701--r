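organ,volume_L,flow_L_per_min
whole_body,53.33333,6.1
arterial_blood,1.21698,
venous_blood,3.08302,
lung,0.31429,6.1
heart_vascular,0.03286,0.244
heart_extravascular,0.18619,
heart_chambers,0.35545,
brain_vascular,0.05876,0.793
muscle,23.07692,0.976
liver,1.2381,1.5555
hepatic_artery,,0.3965
gallbladder,0.045,
gi_tissue,0.95192,0.915
spleen,0.125,0.183
pancreas,0.10577,0.061
kidney_vascular,0.04357,1.159
kidney_extravascular,0.19452,
adipose,13.04348,0.305
thyroid,0.01143,0.0915
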