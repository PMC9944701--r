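{
  "heart_wall": ["heart_vascular", "heart_extravascular"],
  "lungs": ["lung"],
  "liver": ["liver"],
  "gallbladder_contents": ["gallbladder"],
  "intestine_wall": ["gi_tissue"],
  "intestine_contents": ["gi_contents"],
  "kidneys": ["kidney_vascular", "kidney_extravascular"],
  "spleen": ["spleen"],
  "pancreas": ["pancreas"],
  "thyroid": ["thyroid"],
  "bladder_contents": ["bladder"],
  "rest_of_body": ["arterial_blood", "venous_blood", "heart_chambers",
                   "brain_vascular", "muscle", "adipose", "other"],
  "excluded": ["urine"]
}
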